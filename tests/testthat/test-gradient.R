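test_that("3x3 convolution matches the double-loop oracle and flips the kernel", {
  withr::local_seed(31)
  k <- matrix(stats::rnorm(9), 3, 3)
  img <- matrix(stats::runif(64), 8, 8)
  expect_equal(convolve3(img, k), oracle_convolve3(img, k), tolerance = 1e-12)
  expect_equal(convolve3(img, matrix(0, 3, 3)), matrix(0, 8, 8))
  # a delta image is the convolution identity: the kernel is imprinted as-is
  # (under correlation it would come out flipped)
  delta <- matrix(0, 5, 5); delta[3, 3] <- 1
  out <- convolve3(delta, k)
  expect_equal(out[2:4, 2:4], k)
  expect_error(convolve3(img, matrix(1, 2, 2)), class = "pectoseg_shape_error")
})

test_that("a vertical unit step produces the hand-computed Prewitt response", {
  step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  g <- gradient(step, "prewitt")
  # the three kernel rows each contribute 1 at the two columns astride the step
  expect_equal(unique(abs(g$gx[, 4])), 3)
  expect_equal(unique(abs(g$gx[, 5])), 3)
  expect_true(all(g$gx[, c(1:3, 6:8)] == 0))
  expect_true(all(g$gy == 0))
  expect_equal(g$magnitude, abs(g$gx))
  expect_equal(max(g$norm_magnitude), 1)
  expect_equal(gradient(step)$gx,
               oracle_convolve3(step, pectoseg:::edge_kernels()$kx),
               tolerance = 1e-12)
})

test_that("transposing the image exchanges the gradient axes", {
  withr::local_seed(32)
  img <- matrix(stats::runif(100), 10, 10)
  g <- gradient(img)
  gt <- gradient(t(img))
  expect_equal(gt$gx, t(g$gy), tolerance = 1e-12)
  expect_equal(gt$gy, t(g$gx), tolerance = 1e-12)
  expect_equal(gt$magnitude, t(g$magnitude), tolerance = 1e-12)
})

test_that("L1 and Euclidean magnitudes satisfy the norm-equivalence bounds", {
  withr::local_seed(33)
  for (i in 1:5) {
    g <- gradient(matrix(stats::runif(15 * 12), 15, 12))
    expect_true(all(g$magnitude >= 0))
    expect_true(all(g$l1_magnitude >= g$magnitude - 1e-12))
    expect_true(all(g$l1_magnitude <= sqrt(2) * g$magnitude + 1e-12))
    expect_true(all(g$angle > -pi & g$angle <= pi))
  }
  gc <- gradient(matrix(0.5, 6, 6))
  expect_true(all(gc$magnitude == 0) && all(gc$angle == 0))
})

test_that("threshold selection follows the cumulative histogram", {
  gf <- structure(list(norm_magnitude = matrix(c(rep(0.1, 99), 0.9), 10, 10)),
                  class = "gradient_field")
  tau <- select_threshold(gf, 0.01)
  expect_gte(tau, 0.1); expect_lt(tau, 0.9)
  expect_equal(sum(gf$norm_magnitude > tau), 1)

  withr::local_seed(34)
  gf2 <- structure(list(norm_magnitude = matrix(stats::runif(1e4), 100, 100)),
                   class = "gradient_field")
  tau2 <- select_threshold(gf2, 0.25)
  frac <- mean(gf2$norm_magnitude > tau2)
  expect_gte(frac, 0.24); expect_lte(frac, 0.25)

  # near-1 edge_fraction lets almost everything pass
  tau3 <- select_threshold(gf2, 0.999)
  expect_gt(mean(gf2$norm_magnitude > tau3), 0.99)

  # sparse gradients: quantile hits 0 but tau must stay in (0,1) with the
  # same pass set
  sparse <- matrix(0, 10, 10); sparse[5, 5] <- 1; sparse[5, 6] <- 0.5
  gf4 <- structure(list(norm_magnitude = sparse), class = "gradient_field")
  tau4 <- select_threshold(gf4, 0.10)
  expect_gt(tau4, 0); expect_lt(tau4, 1)
  expect_equal(sum(sparse > tau4), 2)

  expect_error(select_threshold(structure(list(norm_magnitude = matrix(0.5, 4, 4)),
                                          class = "gradient_field"), 0.1),
               class = "pectoseg_degenerate_gradient_error")
  expect_error(select_threshold(gf2, 1.5), class = "pectoseg_config_error")
})

test_that("edge maps use strict inequality and are antitone in tau", {
  step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  g <- gradient(step)
  em <- edge_map(g, 0.5)
  expect_equal(which(em$pixels == 1, arr.ind = TRUE)[, 2],
               rep(c(4L, 5L), each = 8L), ignore_attr = TRUE)
  expect_equal(sum(edge_map(g, 0.999)$pixels), 16)  # strict: 1 > 0.999
  withr::local_seed(35)
  g2 <- gradient(matrix(stats::runif(144), 12, 12))
  taus <- sort(stats::runif(5, 0.05, 0.95))
  for (i in seq_len(4)) {
    lo <- edge_map(g2, taus[i])$pixels
    hi <- edge_map(g2, taus[i + 1])$pixels
    expect_true(all(hi <= lo))
  }
  expect_error(edge_map(g2, 0), class = "pectoseg_config_error")
  expect_error(edge_map(g2, 1), class = "pectoseg_config_error")
  expect_error(gradient(step, "roberts"), class = "pectoseg_config_error")
})
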