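#' 3x3 convolution with edge replication
#'
#' True convolution (the kernel is flipped in both directions) of an image
#' with a 3x3 mask. The border is handled by edge replication: the outermost
#' row/column is repeated outward, so a region flush with the image frame
#' produces no spurious frame edge — mammogram breast bodies touch the
#' chest-wall border, and zero padding would paint a false boundary there.
#'
#' @param image Numeric matrix (at least 3x3).
#' @param kernel 3x3 numeric matrix.
#' @return Numeric matrix of the same shape as `image`.
#' @export
convolve3 <- function(image, kernel) {
  if (!is.matrix(image) || nrow(image) < 3L || ncol(image) < 3L)
    abort_pectoseg("pectoseg_shape_error", "`image` must be at least 3x3")
  if (!is.matrix(kernel) || !identical(dim(kernel), c(3L, 3L)))
    abort_pectoseg("pectoseg_shape_error", "`kernel` must be 3x3")
  nr <- nrow(image); nc <- ncol(image)
  pad <- image[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  out <- matrix(0, nr, nc)
  # out[i,j] = sum_{u,v in -1..1} kernel[2+u, 2+v] * image[i-u, j-v]
  for (u in -1:1) for (v in -1:1) {
    out <- out + kernel[2L + u, 2L + v] *
      pad[seq_len(nr) + 1L - u, seq_len(nc) + 1L - v]
  }
  out
}

# Kernel pairs as *convolution* kernels. gx responds to horizontal intensity
# change (vertical edges, increasing column index), gy to vertical change
# (horizontal edges, increasing row index).
edge_kernels <- function(operator = c("prewitt", "sobel")) {
  operator <- match.arg(operator)
  if (operator == "prewitt") {
    kx <- matrix(c(1, 1, 1,  0, 0, 0,  -1, -1, -1), 3, 3)      # columns -1,0,1
    ky <- t(kx)
  } else {
    kx <- matrix(c(1, 2, 1,  0, 0, 0,  -1, -2, -1), 3, 3)
    ky <- t(kx)
  }
  list(kx = kx, ky = ky)
}

#' Differential-operator gradient field
#'
#' Computes the horizontal and vertical 3x3 difference responses (Prewitt by
#' default; Sobel as the alternative the same mask family offers), the
#' Euclidean gradient magnitude `sqrt(gx^2 + gy^2)`, the L1 magnitude
#' `|gx| + |gy|`, and the quadrant-aware gradient angle `atan2(gy, gx)` in
#' (-pi, pi\]. The `norm_magnitude` field is the magnitude globally rescaled
#' to maximum 1 so that edge thresholds in (0, 1) are comparable across
#' images; for a constant image it is identically 0.
#'
#' @param image Grayscale matrix in \[0, 1\].
#' @param operator `"prewitt"` (default) or `"sobel"`. The Prewitt operator
#'   responds best to the near-vertical chest-wall boundary of the pectoral
#'   muscle.
#' @return A `gradient_field` list with fields `gx`, `gy`, `magnitude`,
#'   `l1_magnitude`, `angle`, `norm_magnitude`, `operator`.
#' @examples
#' step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
#' g <- gradient(step)
#' range(g$norm_magnitude)
#' @export
gradient <- function(image, operator = c("prewitt", "sobel")) {
  assert_gray_image(image)
  if (is.character(operator) && length(operator) == 1L &&
      !operator %in% c("prewitt", "sobel"))
    abort_pectoseg("pectoseg_config_error",
                   sprintf("unknown operator '%s'", operator))
  operator <- match.arg(operator)
  k <- edge_kernels(operator)
  gx <- convolve3(image, k$kx)
  gy <- convolve3(image, k$ky)
  mag <- sqrt(gx^2 + gy^2)
  l1 <- abs(gx) + abs(gy)
  ang <- atan2(gy, gx)
  mx <- max(mag)
  norm <- if (mx > 0) mag / mx else mag
  structure(list(gx = gx, gy = gy, magnitude = mag, l1_magnitude = l1,
                 angle = ang, norm_magnitude = norm, operator = operator),
            class = "gradient_field")
}

#' Edge threshold from the cumulative gradient histogram
#'
#' Selects the threshold tau as the (1 - `edge_fraction`) quantile of the
#' normalized gradient magnitudes, so that at most `edge_fraction` of the
#' pixels — those with the largest gradients — are declared edges, and that
#' fraction is maximal under the bound. When the quantile lands on 0 (flat
#' images with sparse boundaries) tau is instead set to half the smallest
#' positive magnitude: the set of passing pixels is unchanged and tau stays
#' inside (0, 1) as the edge-map definition requires.
#'
#' @param grad A `gradient_field` from [gradient()].
#' @param edge_fraction Target fraction of edge pixels in (0, 1);
#'   default 0.10.
#' @return The threshold tau in (0, 1).
#' @export
select_threshold <- function(grad, edge_fraction = 0.10) {
  if (!inherits(grad, "gradient_field"))
    abort_pectoseg("pectoseg_config_error", "`grad` must be a gradient_field")
  if (edge_fraction <= 0 || edge_fraction >= 1)
    abort_pectoseg("pectoseg_config_error", "`edge_fraction` must be in (0, 1)")
  v <- as.vector(grad$norm_magnitude)
  if (max(v) == min(v))
    abort_pectoseg("pectoseg_degenerate_gradient_error",
                   "gradient magnitude is constant; no threshold separates edges")
  s <- sort(v)
  n <- length(s)
  k <- floor(edge_fraction * n)          # max number of pixels allowed to pass
  tau <- if (k == 0L) s[n] else s[n - k]
  # Strict inequality phi > tau may pass fewer than k pixels under ties;
  # that satisfies "<= edge_fraction and maximal" because any smaller tau
  # would pass the whole tie block.
  if (tau <= 0) {
    pos <- v[v > 0]
    tau <- min(pos) / 2
  }
  if (tau >= 1) tau <- 1 - .Machine$double.eps  # max magnitude is exactly 1
  tau
}

#' Threshold the gradient into a binary edge map
#'
#' A pixel is an edge iff its normalized gradient magnitude strictly exceeds
#' tau.
#'
#' @param grad A `gradient_field`.
#' @param tau Threshold in (0, 1).
#' @return An `edge_map` list: `pixels` (binary matrix) and `tau`.
#' @export
edge_map <- function(grad, tau) {
  if (!inherits(grad, "gradient_field"))
    abort_pectoseg("pectoseg_config_error", "`grad` must be a gradient_field")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    abort_pectoseg("pectoseg_config_error", "`tau` must lie strictly in (0, 1)")
  structure(list(pixels = (grad$norm_magnitude > tau) * 1, tau = tau),
            class = "edge_map")
}
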