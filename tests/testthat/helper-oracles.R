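# Independent brute-force oracles. These deliberately restate the set/sum
# definitions directly and share no code with the implementation.

# True 3x3 convolution with replicate padding, one pixel at a time.
oracle_convolve3 <- function(image, kernel) {
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (u in -1:1) for (v in -1:1) {
      ii <- min(max(i - u, 1L), nr)
      jj <- min(max(j - v, 1L), nc)
      acc <- acc + kernel[2L + u, 2L + v] * image[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

disk_offsets <- function(radius) {
  d <- -radius:radius
  which(outer(d^2, d^2, "+") <= radius^2, arr.ind = TRUE) - radius - 1L
}

# Dilation as the union of translates (outside the frame = background).
oracle_dilate <- function(mask, radius) {
  off <- disk_offsets(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i - off[, 1L]; jj <- j - off[, 2L]
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    if (any(mask[cbind(ii[ok], jj[ok])] == 1)) out[i, j] <- 1
  }
  out
}

# Erosion with the footprint clipped at the frame.
oracle_erode <- function(mask, radius) {
  off <- disk_offsets(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + off[, 1L]; jj <- j + off[, 2L]
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    if (all(mask[cbind(ii[ok], jj[ok])] == 1)) out[i, j] <- 1
  }
  out
}

# Ideal full-plane closing restricted to the frame: work on a padded copy
# with plain (unclipped) set-definition dilation/erosion, then crop.
oracle_close <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- matrix(0, nr + 2L * radius, nc + 2L * radius)
  big[radius + seq_len(nr), radius + seq_len(nc)] <- mask
  off <- disk_offsets(radius)
  dil <- matrix(0, nrow(big), ncol(big))
  for (i in seq_len(nrow(big))) for (j in seq_len(ncol(big))) {
    ii <- i - off[, 1L]; jj <- j - off[, 2L]
    ok <- ii >= 1L & ii <= nrow(big) & jj >= 1L & jj <= ncol(big)
    if (any(big[cbind(ii[ok], jj[ok])] == 1)) dil[i, j] <- 1
  }
  ero <- matrix(0, nrow(big), ncol(big))
  for (i in seq_len(nrow(big))) for (j in seq_len(ncol(big))) {
    ii <- i + off[, 1L]; jj <- j + off[, 2L]
    inside <- ii >= 1L & ii <= nrow(big) & jj >= 1L & jj <= ncol(big)
    vals <- ifelse(inside, dil[cbind(pmin(pmax(ii, 1L), nrow(big)),
                                     pmin(pmax(jj, 1L), ncol(big)))], 0)
    if (all(vals == 1)) ero[i, j] <- 1
  }
  ero[radius + seq_len(nr), radius + seq_len(nc)]
}

# Jarvis march (gift wrapping) over (row, col) points; returns hull
# vertices. Independent of grDevices::chull.
oracle_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- order(pts[, 1L], pts[, 2L])[1L]  # topmost, then leftmost
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (n > 1L) setdiff(seq_len(n), cur) else integer(0)
    best <- cand[1L]
    for (k in cand[-1L]) {
      cross <- (pts[best, 1L] - pts[cur, 1L]) * (pts[k, 2L] - pts[cur, 2L]) -
               (pts[best, 2L] - pts[cur, 2L]) * (pts[k, 1L] - pts[cur, 1L])
      if (cross < 0) best <- k
      else if (cross == 0) {
        d_best <- sum((pts[best, ] - pts[cur, ])^2)
        d_k <- sum((pts[k, ] - pts[cur, ])^2)
        if (d_k > d_best) best <- k
      }
    }
    cur <- best
    if (cur == start || length(hull) > n) break
  }
  pts[hull, , drop = FALSE]
}

# All-pairs symmetric Hausdorff distance.
oracle_hausdorff <- function(a, b) {
  dmin_a <- apply(a, 1L, function(p)
    min(sqrt((p[1L] - b[, 1L])^2 + (p[2L] - b[, 2L])^2)))
  dmin_b <- apply(b, 1L, function(p)
    min(sqrt((p[1L] - a[, 1L])^2 + (p[2L] - a[, 2L])^2)))
  max(max(dmin_a), max(dmin_b))
}

rand_mask <- function(nr, nc, p = 0.4) {
  matrix(as.numeric(stats::runif(nr * nc) < p), nr, nc)
}

# Canonical string form of a point set, for order-free comparison.
pts_key <- function(pts) {
  pts <- unique(round(pts, 9))
  paste(sort(paste(pts[, 1L], pts[, 2L])), collapse = ";")
}
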