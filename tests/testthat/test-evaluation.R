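test_that("confusion cells match the 16-pixel hand count and sum to the image", {
  gt <- matrix(0, 4, 4); gt[, 1:2] <- 1   # left half
  seg <- matrix(0, 4, 4); seg[1:2, ] <- 1 # top half
  cells <- confusion_cells(gt, seg)
  expect_equal(cells$w11, 4)  # TP: top-left quadrant
  expect_equal(cells$w21, 4)  # FP: top-right quadrant
  expect_equal(cells$w22, 4)  # FN: bottom-left quadrant
  expect_equal(cells$w12, 4)  # TN: bottom-right quadrant
  expect_equal(cells$fp_pct, 50)
  expect_equal(cells$fn_pct, 50)

  same <- confusion_cells(gt, gt)
  expect_equal(same$w21 + same$w22, 0)
  expect_equal(same$w11, sum(gt))
  expect_equal(confusion_cells(gt, 1 - gt)$w11, 0)
  expect_error(confusion_cells(matrix(0, 4, 4), seg),
               class = "pectoseg_undefined_fn_error")
})

test_that("cell counts always partition the pixel grid", {
  withr::local_seed(81)
  for (i in 1:20) {
    nr <- sample(4:12, 1); nc <- sample(4:12, 1)
    gt <- rand_mask(nr, nc, 0.5); if (!any(gt == 1)) gt[1, 1] <- 1
    seg <- rand_mask(nr, nc, 0.5)
    cells <- confusion_cells(gt, seg)
    expect_equal(cells$w11 + cells$w12 + cells$w21 + cells$w22, nr * nc)
  }
})

test_that("Hausdorff distance matches closed forms and the all-pairs oracle", {
  expect_equal(hausdorff_distance(cbind(0, 0), cbind(3, 4)), 5)
  a <- cbind(c(1, 5, 9), c(2, 2, 2))
  expect_equal(hausdorff_distance(a, a), 0)
  withr::local_seed(82)
  for (i in 1:10) {
    x <- cbind(stats::runif(20, 0, 30), stats::runif(20, 0, 30))
    y <- cbind(stats::runif(15, 0, 30), stats::runif(15, 0, 30))
    expect_equal(hausdorff_distance(x, y), oracle_hausdorff(x, y),
                 tolerance = 1e-12)
  }
  expect_error(hausdorff_distance(matrix(numeric(0), 0, 2), cbind(1, 1)),
               class = "pectoseg_empty_set_error")
})

test_that("Hausdorff distance is a metric on finite point sets", {
  withr::local_seed(83)
  for (i in 1:10) {
    x <- cbind(stats::runif(8, 0, 10), stats::runif(8, 0, 10))
    y <- cbind(stats::runif(8, 0, 10), stats::runif(8, 0, 10))
    z <- cbind(stats::runif(8, 0, 10), stats::runif(8, 0, 10))
    expect_equal(hausdorff_distance(x, y), hausdorff_distance(y, x))
    expect_lte(hausdorff_distance(x, z),
               hausdorff_distance(x, y) + hausdorff_distance(y, z) + 1e-12)
    expect_lte(hausdorff_distance(x, y, directed = TRUE),
               hausdorff_distance(x, y))
  }
})

test_that("category bins tile the FP/FN plane with no overlap or gap", {
  expect_equal(as.integer(categorize_overlap(0, 0)), 1L)
  expect_equal(as.integer(categorize_overlap(3, 7)), 2L)
  for (fp in 0:15) for (fn in 0:15) {
    bin <- as.integer(categorize_overlap(fp, fn))
    lo <- min(fp, fn); hi <- max(fp, fn)
    membership <- c(hi < 5,
                    lo < 5 && hi >= 5 && hi < 10,
                    lo < 5 && hi >= 10,
                    lo >= 5 && hi < 10,
                    lo >= 5 && lo < 10 && hi >= 10,
                    lo >= 10)
    expect_equal(sum(membership), 1L)
    expect_equal(bin, which(membership))
  }
  expect_equal(as.integer(categorize_overlap(NA, 3)), 7L)
})

test_that("visual grades follow the residual-fraction cutpoints", {
  gt <- matrix(0, 10, 10); gt[1:5, 1:4] <- 1  # 20 px muscle
  sil0 <- matrix(0, 10, 10); sil0[6:10, ] <- 1
  expect_equal(as.character(grade_segmentation(sil0, gt)), "successful")
  sil <- sil0; sil[1:2, 1:2] <- 1             # residual 4/20 = 0.2
  expect_equal(as.character(grade_segmentation(sil, gt)), "acceptable")
  sil2 <- sil0; sil2[1:4, 1:3] <- 1           # residual 12/20 = 0.6
  expect_equal(as.character(grade_segmentation(sil2, gt)), "unacceptable")
  expect_error(grade_segmentation(sil0, matrix(0, 10, 10)),
               class = "pectoseg_undefined_grade_error")
})

test_that("cohort summaries aggregate reports coherently", {
  ph <- make_phantom(phantom_spec(noise_sigma = 0, seed = 84))
  rep1 <- evaluate_segmentation(segment_breast(ph$image), ph$pectoral_gt)
  s1 <- summarize_cohort(list(rep1))
  expect_equal(s1$fp_mean, rep1$cells$fp_pct)
  expect_equal(s1$hd_std, 0)
  expect_equal(unname(s1$bin_percentages[as.integer(rep1$category)]), 100)
  expect_equal(sum(s1$bin_percentages), 100)

  rep2 <- rep1; rep2$hausdorff_mm <- rep1$hausdorff_mm + 2
  s2 <- summarize_cohort(list(rep1, rep2))
  expect_equal(s2$hd_mean, rep1$hausdorff_mm + 1)
  expect_equal(s2$hd_std, 1)  # population std of {x, x+2}
  expect_error(summarize_cohort(list()), class = "pectoseg_empty_cohort_error")
})

test_that("hausdorff in mm respects the pixel spacing", {
  ph <- make_phantom(phantom_spec(noise_sigma = 0, seed = 85))
  res <- segment_breast(ph$image)
  e1 <- evaluate_segmentation(res, ph$pectoral_gt, pixel_spacing = 0.2)
  e2 <- evaluate_segmentation(res, ph$pectoral_gt, pixel_spacing = 0.4)
  expect_equal(e2$hausdorff_mm, 2 * e1$hausdorff_mm)
})
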