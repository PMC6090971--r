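#' Synthetic MLO phantom specification
#'
#' Parameters of the synthetic mediolateral-oblique phantom: a dark
#' background, a bright half-elliptical breast body flush with the
#' chest-wall border (spanning the full image height there, as in real MLO
#' positioning), a brighter triangular pectoral wedge in the top chest-wall
#' corner, small high-intensity label blobs near the opposite border, and
#' additive Gaussian noise. The pectoral boundary is a straight line at
#' `pectoral_angle` degrees from the top border — the 45–90 degree
#' anatomical range — optionally bowed by `curvature`. Intensity ordering
#' pectoral > breast > background is enforced, mirroring the muscle's
#' characteristic brightness.
#'
#' @param shape `(height, width)` in pixels; default `c(256, 256)` keeps
#'   whole-cohort runs fast while preserving the geometry of 1024-scale
#'   scans.
#' @param orientation `"left"` (pectoral top-left) or `"right"` (mirrored).
#' @param pectoral_angle Chest-wall boundary angle in degrees, in
#'   \[45, 90\]; `NA` paints no pectoral muscle at all.
#' @param pectoral_intensity,breast_intensity,background_intensity
#'   Intensities in \[0, 1\], strictly decreasing in that order.
#' @param n_labels Number of radiopaque label blobs (default 2).
#' @param label_intensity Label blob intensity (default 0.95).
#' @param noise_sigma Additive Gaussian noise standard deviation
#'   (default 0.02).
#' @param curvature Pectoral-edge bow, as a fraction of image width
#'   displaced at mid-course (0 = straight chord).
#' @param seed Integer seed; phantoms are bit-reproducible for a fixed
#'   spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(256L, 256L),
                         orientation = c("left", "right"),
                         pectoral_angle = 60,
                         pectoral_intensity = 0.75,
                         breast_intensity = 0.45,
                         background_intensity = 0.05,
                         n_labels = 2L,
                         label_intensity = 0.95,
                         noise_sigma = 0.02,
                         curvature = 0,
                         seed = 0L) {
  orientation <- match.arg(orientation)
  if (length(shape) != 2L || any(shape < 32L))
    abort_pectoseg("pectoseg_config_error", "`shape` must be (height, width) >= 32")
  if (!is.na(pectoral_angle) &&
      (pectoral_angle < 45 || pectoral_angle > 90))
    abort_pectoseg("pectoseg_config_error",
                   "`pectoral_angle` must lie in [45, 90] (or NA for none)")
  if (!(pectoral_intensity > breast_intensity &&
        breast_intensity > background_intensity))
    abort_pectoseg("pectoseg_config_error",
                   "need pectoral_intensity > breast_intensity > background_intensity")
  if (noise_sigma < 0)
    abort_pectoseg("pectoseg_config_error", "`noise_sigma` must be >= 0")
  structure(list(shape = as.integer(shape), orientation = orientation,
                 pectoral_angle = pectoral_angle,
                 pectoral_intensity = pectoral_intensity,
                 breast_intensity = breast_intensity,
                 background_intensity = background_intensity,
                 n_labels = as.integer(n_labels),
                 label_intensity = label_intensity,
                 noise_sigma = noise_sigma,
                 curvature = curvature,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic MLO phantom with exact ground truth
#'
#' Paints the phantom described by the spec and returns it together with the
#' exact ground-truth masks used for painting (recorded before noise is
#' added): `breast_gt` (breast tissue excluding the muscle), `pectoral_gt`,
#' and `label_gt`. With `noise_sigma = 0` and `n_labels = 0` the image takes
#' exactly the three painted intensity values, and the masks partition the
#' painted regions exactly by intensity level.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom` list: `image`, `breast_gt`, `pectoral_gt`,
#'   `label_gt`, `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(noise_sigma = 0, n_labels = 0))
#' length(unique(as.vector(ph$image)))
#' @export
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec"))
    abort_pectoseg("pectoseg_config_error", "`spec` must be a phantom_spec()")
  h <- spec$shape[1L]; w <- spec$shape[2L]
  withr::with_seed(spec$seed, {
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)

    # Breast: half-ellipse flush with the chest wall (column 1), tall enough
    # (semi-axis 0.80 h) to span the full height at the chest wall.
    ry <- 0.80 * h; rx <- 0.62 * w
    breast <- (((rr - h / 2) / ry)^2 + ((cc - 1) / rx)^2 <= 1) * 1

    # Pectoral: wedge below the chord from (1, c0) to (r0, 1); side length
    # 0.5 h, top width from the boundary angle, clamped so the 90-degree
    # limit stays a visible sliver.
    pect <- matrix(0, h, w)
    if (!is.na(spec$pectoral_angle)) {
      r0 <- 0.5 * h
      c0 <- r0 / tan(spec$pectoral_angle * pi / 180)
      c0 <- min(max(c0, 0.04 * w), 0.45 * w)
      t <- (rr - 1) / r0
      chord_col <- 1 + c0 * (1 - t) + spec$curvature * w * sinpi(pmin(pmax(t, 0), 1))
      pect <- (t <= 1 & cc <= chord_col) * 1
      pect <- pect * breast
    }
    breast_gt <- breast * (1 - pect)

    # Labels: small bright rectangles in the background near the border
    # opposite the chest wall.
    label_gt <- matrix(0, h, w)
    if (spec$n_labels > 0L) {
      for (i in seq_len(spec$n_labels)) {
        lh <- sample(6:14, 1L); lw <- sample(6:14, 1L)
        top <- sample(seq_len(h - lh), 1L)
        left_min <- min(floor(0.82 * w), w - lw)
        left <- sample(seq(left_min, w - lw), 1L)
        label_gt[top:(top + lh - 1L), left:(left + lw - 1L)] <- 1
      }
      label_gt <- label_gt * (1 - breast)  # never overlap the body
    }

    img <- matrix(spec$background_intensity, h, w)
    img[breast_gt == 1] <- spec$breast_intensity
    img[pect == 1] <- spec$pectoral_intensity
    img[label_gt == 1] <- spec$label_intensity
    if (spec$noise_sigma > 0)
      img <- pmin(pmax(img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma),
                                    h, w), 0), 1)

    out <- list(image = img, breast_gt = breast_gt, pectoral_gt = pect,
                label_gt = label_gt, spec = spec)
    if (spec$orientation == "right") {
      flip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
      out[1:4] <- lapply(out[1:4], flip)
    }
    structure(out, class = "phantom")
  })
}

#' Generate a jittered phantom cohort
#'
#' Draws `n` phantoms whose spec fields are independently jittered within
#' the stated ranges under one master seed. Each cohort member gets its own
#' derived seed, so the cohort is reproducible as a whole and each phantom
#' individually.
#'
#' @param n Number of phantoms (>= 1).
#' @param base A [phantom_spec()] providing the unjittered fields.
#' @param jitter Named list of `c(min, max)` ranges for numeric spec fields
#'   (e.g. `list(pectoral_angle = c(45, 90), noise_sigma = c(0, 0.05))`).
#' @param seed Master seed for the cohort.
#' @return List of `phantom` objects.
#' @export
make_cohort <- function(n, base = phantom_spec(),
                        jitter = list(pectoral_angle = c(45, 90)),
                        seed = 1L) {
  if (n < 1L)
    abort_pectoseg("pectoseg_config_error", "`n` must be >= 1")
  jitterable <- c("pectoral_angle", "pectoral_intensity", "breast_intensity",
                  "background_intensity", "label_intensity", "noise_sigma",
                  "curvature")
  bad <- setdiff(names(jitter), jitterable)
  if (length(bad))
    abort_pectoseg("pectoseg_config_error",
                   sprintf("cannot jitter field(s): %s", paste(bad, collapse = ", ")))
  withr::with_seed(as.integer(seed), {
    seeds <- sample.int(.Machine$integer.max, n)
    draws <- lapply(seq_len(n), function(i) {
      vapply(jitter, function(rng) stats::runif(1L, rng[1L], rng[2L]),
             numeric(1))
    })
  })
  lapply(seq_len(n), function(i) {
    sp <- base
    for (nm in names(jitter)) sp[[nm]] <- unname(draws[[i]][nm])
    sp$seed <- seeds[i]
    make_phantom(sp)
  })
}
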