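#' Pipeline configuration
#'
#' Collects every free parameter of the segmentation pipeline. `tau` and
#' `edge_fraction` are mutually exclusive ways to set the edge threshold; by
#' default the threshold is selected from the cumulative gradient histogram
#' with `edge_fraction = 0.10`. The closing radius defaults to the disk that
#' corresponds to 5 px at 1024x1024, scaled to the input height (never below
#' 1). Orientation `"auto"` mirrors right-MLO scans (detected by comparing
#' foreground mass in the left and right halves) so the pectoral corner is
#' always top-left internally; outputs are mirrored back.
#'
#' @param label_cfg A [label_removal_config()].
#' @param operator `"prewitt"` (default) or `"sobel"`.
#' @param edge_fraction Fraction of pixels declared edges, in (0, 1).
#' @param tau Fixed edge threshold in (0, 1), overriding `edge_fraction`.
#' @param close_radius Disk radius for the closing stage; `NULL` (default)
#'   scales with image height.
#' @param orientation `"auto"` (default), `"left"` or `"right"`.
#' @param seed Integer seed reserved for stochastic tie-breaking; the core
#'   path is deterministic.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(label_cfg = label_removal_config(),
                            operator = c("prewitt", "sobel"),
                            edge_fraction = 0.10, tau = NULL,
                            close_radius = NULL,
                            orientation = c("auto", "left", "right"),
                            seed = 0L) {
  operator <- match.arg(operator)
  orientation <- match.arg(orientation)
  if (!is.null(tau) && (tau <= 0 || tau >= 1))
    abort_pectoseg("pectoseg_config_error", "`tau` must be in (0, 1)")
  if (edge_fraction <= 0 || edge_fraction >= 1)
    abort_pectoseg("pectoseg_config_error", "`edge_fraction` must be in (0, 1)")
  structure(list(label_cfg = label_cfg, operator = operator,
                 edge_fraction = edge_fraction, tau = tau,
                 close_radius = close_radius, orientation = orientation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

default_close_radius <- function(height) {
  max(1L, as.integer(ceiling(5 * height / 1024)))
}

#' Segment the breast profile and remove the pectoral muscle
#'
#' Runs the full pipeline on one MLO scan: label/artifact removal, 3x3
#' gradient and edge thresholding, morphological closing, frame completion
#' (body pixels on the image frame join the closed edge map, since the
#' chest-wall boundary produces no gradient), topographic map and convex
#' hull, gradient-supported pectoral boundary path, shape-shifting
#' silhouette extraction, and the final mapping back to original
#' intensities. Every stage output is retained in the result so the whole
#' intermediate panel sequence can be inspected or written to disk.
#'
#' @param image Grayscale matrix in \[0, 1\].
#' @param cfg A [pipeline_config()].
#' @return A `segmentation_result` list with rasters `original`,
#'   `label_mask`, `clean`, `edge_raw`, `edge_closed`, `hull`, `silhouette`,
#'   `segmented`, `pectoral_mask` (all sharing one shape), plus
#'   `pectoral_curve`, `tau`, `orientation` and `config`.
#' @examples
#' ph <- make_phantom(phantom_spec(noise_sigma = 0))
#' res <- segment_breast(ph$image)
#' sum(res$pectoral_mask) / sum(ph$pectoral_gt)
#' @export
segment_breast <- function(image, cfg = pipeline_config()) {
  assert_gray_image(image)
  if (!inherits(cfg, "pipeline_config"))
    abort_pectoseg("pectoseg_config_error", "`cfg` must be a pipeline_config()")

  stage <- function(name, expr) {
    tryCatch(expr, pectoseg_error = function(e) {
      abort_pectoseg(class(e)[1L], sprintf("[stage %s] %s", name,
                                           conditionMessage(e)))
    })
  }

  rl <- stage("remove_labels", remove_labels(image, cfg$label_cfg))

  orientation <- cfg$orientation
  if (orientation == "auto") {
    half <- ncol(image) %/% 2L
    left_mass <- sum(rl$mask[, seq_len(half)])
    right_mass <- sum(rl$mask) - left_mass
    orientation <- if (right_mass > left_mass) "right" else "left"
  }
  flip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  flipped <- orientation == "right"
  work_image <- if (flipped) flip(image) else image
  mask <- if (flipped) flip(rl$mask) else rl$mask
  clean <- if (flipped) flip(rl$clean) else rl$clean

  g <- stage("gradient", gradient(clean, cfg$operator))
  tau <- if (is.null(cfg$tau))
    stage("select_threshold", select_threshold(g, cfg$edge_fraction))
  else cfg$tau
  em <- stage("edge_map", edge_map(g, tau))

  radius <- if (is.null(cfg$close_radius)) default_close_radius(nrow(image))
            else as.integer(cfg$close_radius)
  closed <- stage("close", mask_close(em$pixels, disk_se(radius)))

  # The chest-wall (and any frame-flush) part of the body outline has no
  # gradient; complete the boundary along the frame before hull building.
  completed <- closed
  frame <- matrix(0, nrow(mask), ncol(mask))
  frame[c(1L, nrow(mask)), ] <- 1
  frame[, c(1L, ncol(mask))] <- 1
  completed <- pmax(completed, frame * mask)

  tm <- stage("topographic_map", topographic_map(completed))
  hull <- stage("convex_hull", convex_hull(tm))
  curve <- stage("pectoral_boundary",
                 pectoral_boundary(closed, "left", gradient_field = g,
                                   body = mask,
                                   exclusion_radius = radius + 2L))
  sil <- stage("shape_shift", shape_shift(hull, mask, curve))
  seg <- stage("apply_silhouette", apply_silhouette(sil, clean))
  pect <- mask * (1 - sil)

  unflip <- function(m) if (flipped) flip(m) else m
  if (flipped && nrow(curve))
    curve[, 2L] <- ncol(image) + 1L - curve[, 2L]
  structure(list(original = image,
                 label_mask = rl$mask,
                 clean = rl$clean,
                 edge_raw = unflip(em$pixels),
                 edge_closed = unflip(closed),
                 hull = unflip(hull$filled),
                 silhouette = unflip(sil),
                 segmented = unflip(seg),
                 pectoral_mask = unflip(pect),
                 pectoral_curve = curve,
                 tau = tau,
                 orientation = orientation,
                 config = cfg),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %dx%d, orientation=%s, tau=%.4g\n",
              nrow(x$original), ncol(x$original), x$orientation, x$tau))
  px <- function(m) sum(m == 1)
  cat(sprintf("  body: %d px | edges: %d raw / %d closed | silhouette: %d px | pectoral: %d px\n",
              px(x$label_mask), px(x$edge_raw), px(x$edge_closed),
              px(x$silhouette), px(x$pectoral_mask)))
  invisible(x)
}

#' Write every stage raster of a segmentation result
#'
#' Dumps the intermediate and final rasters as individual PGM files named by
#' stage (`original.pgm`, `label_mask.pgm`, `clean.pgm`, `edge_raw.pgm`,
#' `edge_closed.pgm`, `hull.pgm`, `silhouette.pgm`, `segmented.pgm`,
#' `pectoral_mask.pgm`).
#'
#' @param result A `segmentation_result`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_result <- function(result, dir) {
  if (!inherits(result, "segmentation_result"))
    abort_pectoseg("pectoseg_config_error", "`result` must be a segmentation_result")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rasters <- c("original", "label_mask", "clean", "edge_raw", "edge_closed",
               "hull", "silhouette", "segmented", "pectoral_mask")
  paths <- vapply(rasters, function(nm) {
    p <- file.path(dir, paste0(nm, ".pgm"))
    write_image(result[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
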