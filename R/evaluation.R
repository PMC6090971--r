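#' Overlap cardinalities of a segmentation against ground truth
#'
#' The 2x2 partition-overlap counts between the ground-truth pectoral region
#' and the predicted one: `w11` = TP (both positive), `w12` = TN (both
#' negative), `w21` = FP (predicted only), `w22` = FN (ground truth only);
#' they always sum to the pixel count. `fp_pct` is FP as a percentage of the
#' ground-truth-negative region and `fn_pct` is FN as a percentage of the
#' ground-truth-positive region.
#'
#' @param gt Ground-truth binary mask (the pectoral partition).
#' @param seg Predicted binary mask.
#' @return A `confusion_cells` list: `w11`, `w12`, `w21`, `w22`, `fp_pct`,
#'   `fn_pct`.
#' @examples
#' gt <- matrix(0, 4, 4); gt[, 1:2] <- 1   # left half
#' seg <- matrix(0, 4, 4); seg[1:2, ] <- 1 # top half
#' confusion_cells(gt, seg)
#' @export
confusion_cells <- function(gt, seg) {
  assert_mask(gt); assert_mask(seg)
  assert_same_shape(gt, seg)
  npos <- sum(gt == 1)
  if (npos == 0)
    abort_pectoseg("pectoseg_undefined_fn_error",
                   "ground-truth positive region is empty; FN% undefined")
  w11 <- sum(gt == 1 & seg == 1)
  w12 <- sum(gt == 0 & seg == 0)
  w21 <- sum(gt == 0 & seg == 1)
  w22 <- sum(gt == 1 & seg == 0)
  structure(list(w11 = w11, w12 = w12, w21 = w21, w22 = w22,
                 fp_pct = 100 * w21 / (length(gt) - npos),
                 fn_pct = 100 * w22 / npos),
            class = "confusion_cells")
}

#' Hausdorff distance between point sets
#'
#' Symmetric Hausdorff distance under the Euclidean metric: the larger of
#' the two directed max-min distances. Used between ground-truth and
#' predicted pectoral boundary points.
#'
#' @param a,b Non-empty n x 2 matrices of (row, col) points.
#' @param directed If `TRUE`, only the directed distance from `a` to `b`.
#' @return Distance in pixel units.
#' @export
hausdorff_distance <- function(a, b, directed = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    abort_pectoseg("pectoseg_empty_set_error", "point sets must be non-empty")
  d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  h_ab <- sqrt(max(apply(d2, 1L, min)))
  if (directed) return(h_ab)
  h_ba <- sqrt(max(apply(d2, 2L, min)))
  max(h_ab, h_ba)
}

#' Boundary points of a binary mask
#'
#' Foreground pixels adjacent (8-connectivity) to an in-image background
#' pixel; segments flush with the image frame are not counted as boundary.
#'
#' @param mask Binary 0/1 matrix.
#' @return n x 2 matrix of (row, col) boundary points.
#' @export
mask_boundary <- function(mask) {
  assert_mask(mask)
  # 8-neighborhood erosion with frame clipping; boundary = mask minus eroded.
  off <- which(matrix(TRUE, 3, 3), arr.ind = TRUE) - 2L
  out <- matrix(1, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- pmin(out, shift_mat(mask, -off[i, 1L], -off[i, 2L], 1))
  which(mask == 1 & out == 0, arr.ind = TRUE)
}

category_labels <- c(
  "FP<5 and FN<5",
  "min<5 and 5<=max<10",
  "min<5 and max>=10",
  "5<=FP<10 and 5<=FN<10",
  "5<=min<10 and max>=10",
  "FP>=10 and FN>=10",
  "undefined"
)

#' Category bin of an FP/FN percentage pair
#'
#' Assigns the pair to exactly one of the seven performance bins used in
#' cohort reporting, from best (both rates under 5%) to worst (both at or
#' above 10%). Interval boundaries are left-closed (`[5, 10)` etc.)
#' uniformly; the seventh bin is reserved for undefined rates (NA).
#'
#' @param fp_pct,fn_pct FP and FN percentages in \[0, 100\], or a
#'   `confusion_cells` object as the first argument.
#' @return Integer bin 1..7 with a `label` attribute.
#' @export
categorize_overlap <- function(fp_pct, fn_pct) {
  if (inherits(fp_pct, "confusion_cells")) {
    fn_pct <- fp_pct$fn_pct
    fp_pct <- fp_pct$fp_pct
  }
  bin <- if (is.na(fp_pct) || is.na(fn_pct)) 7L else {
    lo <- min(fp_pct, fn_pct); hi <- max(fp_pct, fn_pct)
    if (hi < 5) 1L
    else if (lo < 5 && hi < 10) 2L
    else if (lo < 5) 3L
    else if (hi < 10) 4L
    else if (lo < 10) 5L
    else 6L
  }
  structure(bin, label = category_labels[bin])
}

#' Visual grade of a segmentation
#'
#' Three-level grade from the residual pectoral fraction
#' r = |silhouette ∩ ground-truth pectoral| / |ground-truth pectoral|:
#' `successful` when at most 1% of the muscle survives (no undesired parts,
#' with a 1% rasterization allowance), `unacceptable` when half or more
#' survives, `acceptable` in between.
#'
#' @param result A `segmentation_result`, or a binary silhouette mask.
#' @param gt_pectoral Non-empty ground-truth pectoral mask.
#' @return `"successful"`, `"acceptable"` or `"unacceptable"`, with the
#'   residual fraction in attribute `residual`.
#' @export
grade_segmentation <- function(result, gt_pectoral) {
  sil <- if (inherits(result, "segmentation_result")) result$silhouette
         else result
  assert_mask(sil); assert_mask(gt_pectoral)
  assert_same_shape(sil, gt_pectoral)
  npos <- sum(gt_pectoral == 1)
  if (npos == 0)
    abort_pectoseg("pectoseg_undefined_grade_error",
                   "ground-truth pectoral mask is empty")
  r <- sum(sil == 1 & gt_pectoral == 1) / npos
  grade <- if (r <= 0.01) "successful" else if (r < 0.5) "acceptable"
           else "unacceptable"
  structure(grade, residual = r)
}

#' Evaluate one segmentation against ground truth
#'
#' Bundles the overlap cardinalities, the FP/FN category bin, the symmetric
#' Hausdorff distance between ground-truth and predicted pectoral
#' boundaries (in mm via the pixel spacing), and the visual grade.
#'
#' @param result A `segmentation_result`.
#' @param gt_pectoral Ground-truth pectoral mask.
#' @param pixel_spacing mm per pixel (default 0.2, the 200-micron MIAS
#'   digitization).
#' @return An `eval_report` list: `cells`, `hausdorff_mm`, `category`,
#'   `grade`.
#' @export
evaluate_segmentation <- function(result, gt_pectoral, pixel_spacing = 0.2) {
  if (!inherits(result, "segmentation_result"))
    abort_pectoseg("pectoseg_config_error", "`result` must be a segmentation_result")
  cells <- confusion_cells(gt_pectoral, result$pectoral_mask)
  hd <- hausdorff_distance(mask_boundary(gt_pectoral),
                           mask_boundary(result$pectoral_mask)) * pixel_spacing
  structure(list(cells = cells,
                 hausdorff_mm = hd,
                 category = categorize_overlap(cells),
                 grade = grade_segmentation(result, gt_pectoral)),
            class = "eval_report")
}

#' Summarize evaluation reports over a cohort
#'
#' Per-image means of the FP/FN pixel percentages, the percentage of images
#' in each category bin (summing to 100), and the Hausdorff distance as
#' mean and population standard deviation.
#'
#' @param reports Non-empty list of `eval_report` objects.
#' @return A `cohort_summary` list: `n_images`, `fp_mean`, `fn_mean`,
#'   `bin_percentages` (length 7), `hd_mean`, `hd_std`, `grades` (named
#'   counts).
#' @export
summarize_cohort <- function(reports) {
  if (!length(reports))
    abort_pectoseg("pectoseg_empty_cohort_error", "no reports to summarize")
  fp <- vapply(reports, function(r) r$cells$fp_pct, numeric(1))
  fn <- vapply(reports, function(r) r$cells$fn_pct, numeric(1))
  hd <- vapply(reports, function(r) r$hausdorff_mm, numeric(1))
  bins <- vapply(reports, function(r) as.integer(r$category), integer(1))
  grades <- vapply(reports, function(r) as.character(r$grade), character(1))
  bin_pct <- 100 * tabulate(bins, nbins = 7L) / length(reports)
  names(bin_pct) <- category_labels
  structure(list(n_images = length(reports),
                 fp_mean = mean(fp), fn_mean = mean(fn),
                 bin_percentages = bin_pct,
                 hd_mean = mean(hd),
                 hd_std = sqrt(mean((hd - mean(hd))^2)),
                 grades = table(factor(grades, levels = c(
                   "successful", "acceptable", "unacceptable")))),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n=%d images\n", x$n_images))
  cat(sprintf("  FP mean %.2f%% | FN mean %.2f%% | HD %.2f +/- %.2f mm\n",
              x$fp_mean, x$fn_mean, x$hd_mean, x$hd_std))
  for (i in seq_along(x$bin_percentages))
    if (x$bin_percentages[i] > 0)
      cat(sprintf("  %-24s %5.1f%%\n", names(x$bin_percentages)[i],
                  x$bin_percentages[i]))
  invisible(x)
}
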