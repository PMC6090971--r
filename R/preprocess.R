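#' Label-removal configuration
#'
#' Parameters of the label/artifact removal stage. The scan is binarized
#' (Otsu by default, or a fixed intensity threshold), 8-connected components
#' of the foreground are ranked by area, and only the largest
#' `keep_components` are retained — the breast body is by far the largest
#' bright region in an MLO scan, while radiopaque labels and markers are
#' small disjoint blobs. Components whose area falls below
#' `min_area_fraction` of the image are always discarded.
#'
#' @param binarize_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Intensity threshold in \[0, 1\]; used when
#'   `binarize_method = "fixed"`.
#' @param keep_components Number of largest components to keep (default 1).
#' @param min_area_fraction Fraction of the image area in \[0, 1) below which
#'   a component is discarded regardless of rank (default 0).
#' @return A `label_removal_config` list.
#' @export
label_removal_config <- function(binarize_method = c("otsu", "fixed"),
                                 fixed_threshold = 0.5,
                                 keep_components = 1L,
                                 min_area_fraction = 0) {
  binarize_method <- match.arg(binarize_method)
  if (fixed_threshold < 0 || fixed_threshold > 1)
    abort_pectoseg("pectoseg_config_error", "`fixed_threshold` must be in [0, 1]")
  if (keep_components < 1L)
    abort_pectoseg("pectoseg_config_error", "`keep_components` must be >= 1")
  if (min_area_fraction < 0 || min_area_fraction >= 1)
    abort_pectoseg("pectoseg_config_error", "`min_area_fraction` must be in [0, 1)")
  structure(list(binarize_method = binarize_method,
                 fixed_threshold = fixed_threshold,
                 keep_components = as.integer(keep_components),
                 min_area_fraction = min_area_fraction),
            class = "label_removal_config")
}

#' Remove radiopaque labels and machine artifacts
#'
#' First stage of the pipeline. The scan is binarized, the largest
#' high-intensity 8-connected component(s) (the breast body) are kept as the
#' body mask, and the clean grayscale image is the pointwise product of mask
#' and input: pixels inside the mask keep their original intensities
#' bit-exactly, everything else (labels, markers, background) is set to 0.
#' Components touching the image frame are *not* discarded — the breast
#' always touches at least one border in an MLO view.
#'
#' @param image Grayscale matrix in \[0, 1\].
#' @param cfg A [label_removal_config()].
#' @return A list with elements `mask` (binary body mask) and `clean`
#'   (grayscale image, zero outside the mask).
#' @examples
#' ph <- make_phantom(phantom_spec(noise_sigma = 0))
#' out <- remove_labels(ph$image)
#' sum(out$mask)
#' @export
remove_labels <- function(image, cfg = label_removal_config()) {
  assert_gray_image(image)
  if (!inherits(cfg, "label_removal_config"))
    abort_pectoseg("pectoseg_config_error",
                   "`cfg` must be a label_removal_config()")
  thr <- if (cfg$binarize_method == "otsu") {
    if (length(unique(as.vector(image))) < 2L)
      abort_pectoseg("pectoseg_empty_foreground_error",
                     "image is constant; no foreground after binarization")
    EBImage::otsu(image, range = c(0, 1))
  } else {
    cfg$fixed_threshold
  }
  bin <- (image > thr) * 1
  if (!any(bin == 1))
    abort_pectoseg("pectoseg_empty_foreground_error",
                   "no foreground component after binarization")
  lab <- label_components(bin, connectivity = 8L)
  sizes <- component_sizes(lab)
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(cfg$keep_components,
                                                      length(sizes)))]
  keep <- keep[sizes[keep] >= cfg$min_area_fraction * length(image)]
  if (!length(keep))
    abort_pectoseg("pectoseg_empty_foreground_error",
                   "all components below `min_area_fraction`")
  mask <- matrix(as.numeric(lab %in% keep), nrow(image), ncol(image))
  clean <- mask * image
  list(mask = mask, clean = clean)
}
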