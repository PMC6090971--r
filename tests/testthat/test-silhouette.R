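test_that("the topographic map of a filled square is its 8 boundary extremes", {
  m <- matrix(0, 10, 12); m[3:5, 4:6] <- 1
  tm <- topographic_map(m)
  expected <- rbind(c(3, 4), c(3, 5), c(3, 6),
                    c(4, 4), c(4, 6),
                    c(5, 4), c(5, 5), c(5, 6))
  expect_equal(pts_key(tm$points), pts_key(expected))
  expect_equal(tm$source_shape, c(10L, 12L))
})

test_that("degenerate point sets are rejected", {
  m <- matrix(0, 8, 8); m[4, 2:6] <- 1  # single row segment: collinear
  expect_error(topographic_map(m), class = "pectoseg_degenerate_geometry_error")
  m2 <- matrix(0, 8, 8); m2[3, 3] <- 1; m2[5, 5] <- 1  # two pixels
  expect_error(topographic_map(m2), class = "pectoseg_degenerate_geometry_error")
})

test_that("a filled disk's topographic map lies on its boundary ring", {
  m <- matrix(0, 15, 15); m[3:13, 3:13] <- disk_se(5)$footprint
  tm <- topographic_map(m)
  ring <- m - mask_erode(m, disk_se(1))
  expect_true(all(ring[tm$points] == 1))
})

test_that("convex hull vertices match geometry on canonical cases", {
  rect <- rbind(c(2, 2), c(2, 9), c(8, 2), c(8, 9))
  attr(rect, "source_shape") <- c(10L, 10L)
  h <- convex_hull(rect)
  expect_equal(pts_key(h$polygon), pts_key(rect))
  expect_true(all(h$filled[rect] == 1))
  expect_equal(sum(h$filled), 7 * 8)  # the full rectangle raster

  with_interior <- rbind(rect, c(5, 5))
  attr(with_interior, "source_shape") <- c(10L, 10L)
  h2 <- convex_hull(with_interior)
  expect_equal(pts_key(h2$polygon), pts_key(rect))  # interior point dropped

  line <- rbind(c(1, 1), c(2, 2), c(3, 3))
  attr(line, "source_shape") <- c(5L, 5L)
  expect_error(convex_hull(line), class = "pectoseg_degenerate_geometry_error")
})

test_that("hull vertices equal the gift-wrapping oracle on random points", {
  withr::local_seed(61)
  for (i in 1:30) {
    n <- sample(5:30, 1)
    pts <- cbind(stats::runif(n, 1, 15), stats::runif(n, 1, 15))
    attr(pts, "source_shape") <- c(16L, 16L)
    h <- convex_hull(pts)
    expect_equal(pts_key(h$polygon), pts_key(oracle_hull(pts)))
    # every generating point is covered by the fill
    expect_true(all(h$filled[cbind(round(pts[, 1]), round(pts[, 2]))] == 1))
  }
})

test_that("the pectoral path follows a straight chord on a clean phantom", {
  ph <- make_phantom(phantom_spec(noise_sigma = 0, n_labels = 0, seed = 62,
                                  pectoral_angle = 60))
  rl <- remove_labels(ph$image)
  g <- gradient(rl$clean)
  em <- edge_map(g, select_threshold(g, 0.10))
  closed <- mask_close(em$pixels, disk_se(2))
  curve <- pectoral_boundary(closed, "left", gradient_field = g,
                             body = rl$mask, exclusion_radius = 4)
  c0 <- 1 + (0.5 * 256) / tan(60 * pi / 180)
  r0 <- 1 + 0.5 * 256
  top <- curve[1, ]; bottom <- curve[nrow(curve), ]
  expect_equal(top[1], 1)
  expect_lt(abs(top[2] - c0), 3)
  expect_equal(bottom[2], 1)
  expect_lt(abs(bottom[1] - r0), 3)
  expect_true(all(diff(curve[, 1]) >= 0))  # returned top to bottom
})

test_that("edge maps without a top-to-left path yield an empty curve", {
  edges <- matrix(0, 20, 20); edges[10, 3:18] <- 1  # horizontal bar only
  curve <- pectoral_boundary(edges)
  expect_equal(nrow(curve), 0L)
  expect_equal(nrow(pectoral_boundary(matrix(0, 20, 20))), 0L)
})

test_that("of two candidate paths the one with stronger gradient support wins", {
  n <- 40L
  edges <- matrix(0, n, n)
  sup <- matrix(0, n, n)
  for (r in 1:29) {  # strong chord: r + c = 30
    edges[r, 30 - r] <- 1; sup[r, 30 - r] <- 0.9
  }
  for (r in 1:19) {  # weak chord: r + c = 20
    edges[r, 20 - r] <- 1; sup[r, 20 - r] <- 0.3
  }
  gf <- structure(list(norm_magnitude = sup), class = "gradient_field")
  curve <- pectoral_boundary(edges, gradient_field = gf)
  expect_true(all(curve[, 1] + curve[, 2] == 30))
  expect_equal(attr(curve, "mean_support"), 0.9)
})

test_that("shape shifting intersects hull and body, cutting the chest side", {
  m <- matrix(0, 12, 12); m[2:11, 2:11] <- 1
  tm <- topographic_map(m)
  h <- convex_hull(tm)
  none <- shape_shift(h, m)
  expect_equal(none, h$filled * m)  # empty curve removes nothing
  curve <- cbind(3:8, rep(4L, 6))
  cut <- shape_shift(h, m, curve)
  expect_true(all(cut[3:8, 1:4] == 0))
  expect_true(all(cut <= m))
  expect_error(shape_shift(h, m, cbind(2:11, rep(11L, 10))),
               class = "pectoseg_empty_silhouette_error")
})

test_that("silhouette application preserves intensities bit-exactly", {
  withr::local_seed(63)
  img <- matrix(stats::runif(100), 10, 10)
  sil <- rand_mask(10, 10, 0.5)
  out <- apply_silhouette(sil, img)
  loop <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) loop[i, j] <- sil[i, j] * img[i, j]
  expect_equal(out, loop)
  expect_identical(out[sil == 1], img[sil == 1])
  expect_equal(apply_silhouette(matrix(1, 10, 10), img), img)
  expect_equal(apply_silhouette(matrix(0, 10, 10), img), matrix(0, 10, 10))
  expect_error(apply_silhouette(sil, matrix(0.5, 4, 4)),
               class = "pectoseg_shape_error")
})
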