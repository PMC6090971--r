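#' Mean squared error between two images
#'
#' @param ref,test Numeric matrices of the same shape.
#' @return Mean of squared pixelwise differences (intensity^2 units).
#' @export
mse <- function(ref, test) {
  if (!is.matrix(ref) || !is.matrix(test))
    abort_pectoseg("pectoseg_type_error", "inputs must be matrices")
  assert_same_shape(ref, test)
  mean((ref - test)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB; `Inf` when the images are identical
#' (MSE = 0).
#'
#' @param ref,test Numeric matrices of the same shape.
#' @param peak Peak signal value (default 1, the normalized intensity
#'   ceiling).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, peak = 1) {
  if (peak <= 0)
    abort_pectoseg("pectoseg_config_error", "`peak` must be > 0")
  m <- mse(ref, test)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' Structural similarity index
#'
#' Product of luminance, contrast and structure comparison terms,
#' `l^alpha * c^beta * s^gamma`, clamped to \[0, 1\]:
#' \deqn{l = \frac{2\mu_x\mu_y + \epsilon_1}{\mu_x^2 + \mu_y^2 + \epsilon_1},
#'   \quad c = \frac{2\sigma_x\sigma_y + \epsilon_2}
#'                  {\sigma_x^2 + \sigma_y^2 + \epsilon_2},
#'   \quad s = \frac{\sigma_{xy} + \epsilon_3}
#'                  {\sigma_x\sigma_y + \epsilon_3}.}
#' All exponents default to 1. By default the statistics are computed
#' globally over the whole image (the windowless form); `window = "sliding"`
#' averages the index over odd-sized square neighborhoods instead, for
#' parity with common practice. Variances/covariances use the population
#' (1/n) convention. `ssim(x, x)` is exactly 1 for any non-constant `x`.
#'
#' @param ref,test Numeric matrices of the same shape, intensities in
#'   \[0, 1\].
#' @param alpha,beta,gamma Term exponents (default 1).
#' @param eps1,eps2,eps3 Stabilization constants; defaults
#'   `(0.01*peak)^2`, `(0.03*peak)^2`, `eps2/2`.
#' @param peak Peak signal value used for the default constants.
#' @param window `"global"` (default) or `"sliding"`.
#' @param window_size Odd side length of the sliding window (default 11).
#' @return SSIM in \[0, 1\].
#' @export
ssim <- function(ref, test, alpha = 1, beta = 1, gamma = 1,
                 eps1 = (0.01 * peak)^2, eps2 = (0.03 * peak)^2,
                 eps3 = eps2 / 2, peak = 1,
                 window = c("global", "sliding"), window_size = 11L) {
  if (!is.matrix(ref) || !is.matrix(test))
    abort_pectoseg("pectoseg_type_error", "inputs must be matrices")
  assert_same_shape(ref, test)
  window <- match.arg(window)
  if (any(c(eps1, eps2, eps3) <= 0))
    abort_pectoseg("pectoseg_config_error", "stabilization constants must be > 0")
  ssim_terms <- function(mx, my, vx, vy, cxy) {
    l <- (2 * mx * my + eps1) / (mx^2 + my^2 + eps1)
    co <- (2 * sqrt(vx) * sqrt(vy) + eps2) / (vx + vy + eps2)
    st <- (cxy + eps3) / (sqrt(vx) * sqrt(vy) + eps3)
    l^alpha * co^beta * st^gamma
  }
  if (window == "global") {
    n <- length(ref)
    mx <- mean(ref); my <- mean(test)
    vx <- mean((ref - mx)^2); vy <- mean((test - my)^2)
    cxy <- mean((ref - mx) * (test - my))
    val <- ssim_terms(mx, my, vx, vy, cxy)
  } else {
    if (window_size %% 2L != 1L || window_size < 3L)
      abort_pectoseg("pectoseg_config_error", "`window_size` must be odd and >= 3")
    bm <- function(x) box_mean(x, window_size)
    mx <- bm(ref); my <- bm(test)
    vx <- pmax(bm(ref^2) - mx^2, 0)
    vy <- pmax(bm(test^2) - my^2, 0)
    cxy <- bm(ref * test) - mx * my
    val <- mean(ssim_terms(mx, my, vx, vy, cxy))
  }
  min(max(val, 0), 1)
}

# Local box mean with replicate padding, separable 1-D passes.
box_mean <- function(x, k) {
  r <- (k - 1L) %/% 2L
  pad_run <- function(m) {
    nr <- nrow(m)
    m <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
    out <- matrix(0, nr, ncol(m))
    for (d in -r:r) out <- out + m[seq_len(nr) + r + d, , drop = FALSE]
    out / k
  }
  t(pad_run(t(pad_run(x))))
}

#' Rank edge operators by image quality
#'
#' Computes MSE, PSNR and SSIM between the input image and each operator's
#' binary edge response (rendered at intensity 1 on black), the comparison
#' used to choose among the 3x3 mask family. Higher PSNR and SSIM with lower
#' MSE indicate the better-behaved detector for the scan at hand.
#'
#' @param image Grayscale matrix in \[0, 1\].
#' @param operators Character vector of operator names (default both
#'   `"prewitt"` and `"sobel"`).
#' @param edge_fraction Passed to [select_threshold()].
#' @return A data.frame with columns `operator`, `psnr`, `ssim`, `mse`.
#' @export
rank_edge_operators <- function(image, operators = c("prewitt", "sobel"),
                                edge_fraction = 0.10) {
  assert_gray_image(image)
  rows <- lapply(operators, function(op) {
    g <- gradient(image, op)
    em <- edge_map(g, select_threshold(g, edge_fraction))
    data.frame(operator = op,
               psnr = psnr(image, em$pixels),
               ssim = ssim(image, em$pixels),
               mse = mse(image, em$pixels))
  })
  do.call(rbind, rows)
}
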