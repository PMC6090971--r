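#' Topographic map of extremal foreground pixels
#'
#' The "four corners" feature set of a binary image: for every occupied row
#' its leftmost and rightmost foreground pixel, and for every occupied
#' column its topmost and bottommost, deduplicated and returned in raster
#' order. This sparse map carries all the information the convex hull needs,
#' at a fraction of the foreground size.
#'
#' @param mask Binary 0/1 matrix with at least 3 non-collinear foreground
#'   pixels.
#' @return A `topographic_map` list: `points` (n x 2 integer matrix of
#'   (row, col)) and `source_shape`.
#' @export
topographic_map <- function(mask) {
  assert_mask(mask)
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) < 3L)
    abort_pectoseg("pectoseg_degenerate_geometry_error",
                   "mask has fewer than 3 foreground pixels")
  rows <- idx[, 1L]; cols <- idx[, 2L]
  per_row <- do.call(rbind, lapply(split(cols, rows), range))
  row_pts <- cbind(rep(as.integer(rownames(per_row)), 2L),
                   c(per_row[, 1L], per_row[, 2L]))
  per_col <- do.call(rbind, lapply(split(rows, cols), range))
  col_pts <- cbind(c(per_col[, 1L], per_col[, 2L]),
                   rep(as.integer(rownames(per_col)), 2L))
  pts <- unique(rbind(row_pts, col_pts))
  pts <- pts[order(pts[, 1L], pts[, 2L]), , drop = FALSE]
  if (points_collinear(pts))
    abort_pectoseg("pectoseg_degenerate_geometry_error",
                   "foreground pixels are collinear")
  structure(list(points = unname(pts), source_shape = dim(mask)),
            class = "topographic_map")
}

points_collinear <- function(pts) {
  if (nrow(pts) < 3L) return(TRUE)
  p0 <- pts[1L, ]
  d <- sweep(pts[-1L, , drop = FALSE], 2L, p0)
  cross <- d[1L, 1L] * d[, 2L] - d[1L, 2L] * d[, 1L]
  all(cross == 0)
}

#' Convex hull image
#'
#' Minimal convex polygon containing the topographic-map points, plus its
#' raster fill. A pixel belongs to the fill when its center lies inside or
#' on the polygon (with half-pixel tolerance, so every generating point is
#' covered). The filled hull is the "shape-shifting" template that, clipped
#' to the body mask, recovers the breast silhouette.
#'
#' @param map A [topographic_map()], or an n x 2 matrix of (row, col)
#'   points with an attached `source_shape` attribute.
#' @return A `hull_image` list: `polygon` (vertices in counter-clockwise
#'   order as (row, col)) and `filled` (binary matrix).
#' @export
convex_hull <- function(map) {
  if (inherits(map, "topographic_map")) {
    pts <- map$points
    shape <- map$source_shape
  } else {
    pts <- map
    shape <- attr(map, "source_shape")
    if (is.null(shape))
      abort_pectoseg("pectoseg_config_error",
                     "matrix input needs a `source_shape` attribute")
  }
  if (nrow(unique(pts)) < 3L || points_collinear(unique(pts)))
    abort_pectoseg("pectoseg_degenerate_geometry_error",
                   "need at least 3 non-collinear points")
  # chull works in (x, y); use x = col, y = row.
  h <- grDevices::chull(pts[, 2L], pts[, 1L])
  poly <- pts[h, , drop = FALSE]
  # Orient counter-clockwise in (row, col) via the shoelace sign.
  area2 <- sum(poly[, 2L] * c(poly[-1L, 1L], poly[1L, 1L]) -
               c(poly[-1L, 2L], poly[1L, 2L]) * poly[, 1L])
  if (area2 < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  structure(list(polygon = unname(poly),
                 filled = fill_convex_polygon(poly, shape)),
            class = "hull_image")
}

# Rasterize a convex polygon by half-plane tests; `tol` (in pixel units)
# keeps pixels whose center is marginally outside, so the discrete body a
# hull was built around is never clipped by rounding.
fill_convex_polygon <- function(poly, shape, tol = 0.7071) {
  nr <- shape[1L]; nc <- shape[2L]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside <- matrix(TRUE, nr, nc)
  n <- nrow(poly)
  ctr <- colMeans(poly)  # interior point of a convex polygon
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    er <- b[1L] - a[1L]; ec <- b[2L] - a[2L]
    len <- sqrt(er^2 + ec^2)
    if (len == 0) next
    # Signed distance of pixel centers from edge ab, oriented so the
    # centroid side is positive; a consistent winding makes the interior
    # the intersection of the positive half-planes.
    s <- (er * (cc - a[2L]) - ec * (rr - a[1L])) / len
    s_ctr <- (er * (ctr[2L] - a[2L]) - ec * (ctr[1L] - a[1L])) / len
    if (s_ctr < 0) s <- -s
    inside <- inside & (s >= -tol)
  }
  inside * 1
}

#' Chest-wall pectoral boundary path
#'
#' Separates the pectoral edge from the closed edge map: among 8-connected
#' edge paths that start on the top image border and end on the left image
#' border, returns the one with the largest mean gradient support (shorter
#' paths win ties), as the pectoral boundary is the strongest top-to-chest
#' edge in an MLO view. The search runs over the edge-pixel adjacency graph
#' with Dijkstra weights `1 + epsilon - gradient support`, so strong short
#' edges are cheapest. When a body mask is supplied, edge pixels within
#' `exclusion_radius` of the body's interior-facing boundary (the skin line)
#' are excluded from the graph so the breast outline is never mistaken for
#' the muscle boundary. An empty result is a valid outcome (pectoral-free
#' image).
#'
#' @param edges Closed binary edge map, orientation normalized so the
#'   pectoral corner is top-left.
#' @param orientation `"left"` (default) or `"right"`; `"right"` inputs are
#'   mirrored internally and the returned curve mirrored back.
#' @param gradient_field Optional [gradient()] result providing the support
#'   weights; without it all edges weigh equally and the shortest path wins.
#' @param body Optional binary body mask used for skin-line exclusion.
#' @param exclusion_radius Width in pixels of the skin-line exclusion band
#'   (default 4).
#' @return An m x 2 matrix of (row, col) path pixels ordered from the top
#'   border to the left border, with attribute `mean_support`; a 0 x 2
#'   matrix if no such path exists.
#' @export
pectoral_boundary <- function(edges, orientation = c("left", "right"),
                              gradient_field = NULL, body = NULL,
                              exclusion_radius = 4L) {
  assert_mask(edges)
  orientation <- match.arg(orientation)
  if (orientation == "right") {
    flip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
    g2 <- gradient_field
    if (!is.null(g2)) g2$norm_magnitude <- flip(g2$norm_magnitude)
    curve <- pectoral_boundary(flip(edges), "left", g2,
                               if (is.null(body)) NULL else flip(body),
                               exclusion_radius)
    if (nrow(curve)) curve[, 2L] <- ncol(edges) + 1L - curve[, 2L]
    return(curve)
  }
  keep <- edges == 1
  if (!is.null(body)) {
    assert_mask(body)
    assert_same_shape(edges, body)
    interior <- mask_erode(body, disk_se(as.integer(exclusion_radius)))
    keep <- keep & interior == 1
  }
  empty <- matrix(integer(0), 0L, 2L)
  keepm <- keep * 1
  if (!any(keepm == 1)) return(structure(empty, mean_support = NA_real_))
  support_map <- if (is.null(gradient_field)) keepm else
    gradient_field$norm_magnitude

  # A candidate path must run from the top border to the left border, and
  # its chest-wall end must sit at least `min_chest_row` rows down: the
  # muscle always spans a substantial fraction of the image height, and
  # without this constraint a single noise pixel at the very corner (which
  # touches both borders at once) would qualify. The winner maximizes
  # gradient support; optimizing the mean directly is ill-posed (trivial
  # near-corner paths dominate), so the bottleneck (maximin) criterion is
  # used: binary-search the largest support level at which the two borders
  # stay 8-connected, then take the shortest path inside that strongest
  # subgraph (the spec'd tie-break).
  min_chest_row <- max(2L, as.integer(round(nrow(edges) / 8)))
  connects <- function(m) {
    if (!any(m[1L, ] == 1) || !any(m[, 1L] == 1)) return(FALSE)
    lab <- label_components(m, connectivity = 8L)
    deep_left <- lab[min_chest_row:nrow(m), 1L]
    any(lab[1L, ][lab[1L, ] > 0L] %in% deep_left[deep_left > 0L])
  }
  if (!connects(keepm)) return(structure(empty, mean_support = NA_real_))
  levels <- sort(unique(support_map[keepm == 1]))
  if (length(levels) > 64L)
    levels <- unique(stats::quantile(support_map[keepm == 1],
                                     probs = seq(0, 1, length.out = 64L),
                                     names = FALSE, type = 1L))
  lo <- 1L; hi <- length(levels)   # levels[lo] always connects
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (connects(keepm * (support_map >= levels[mid]))) lo <- mid else hi <- mid - 1L
  }
  strong <- keepm * (support_map >= levels[lo])

  idx <- which(strong == 1)
  nr <- nrow(edges)
  pos <- arrayInd(idx, dim(edges))
  node_id <- match(seq_len(length(edges)), idx)  # linear index -> node or NA
  support <- support_map[idx]
  top_nodes <- which(pos[, 1L] == 1L)
  left_nodes <- which(pos[, 2L] == 1L & pos[, 1L] >= min_chest_row)

  # 8-neighbor adjacency among kept pixels (4 undirected direction classes).
  shifts <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  from <- integer(0); to <- integer(0)
  for (s in seq_len(nrow(shifts))) {
    nb_r <- pos[, 1L] + shifts[s, 1L]
    nb_c <- pos[, 2L] + shifts[s, 2L]
    ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= ncol(edges)
    nb_lin <- (nb_c[ok] - 1L) * nr + nb_r[ok]
    nb_node <- node_id[nb_lin]
    has <- !is.na(nb_node)
    from <- c(from, which(ok)[has])
    to <- c(to, nb_node[has])
  }
  n_nodes <- length(idx)
  src <- n_nodes + 1L
  snk <- n_nodes + 2L
  edge_list <- rbind(cbind(from, to),
                     cbind(rep(src, length(top_nodes)), top_nodes),
                     cbind(rep(snk, length(left_nodes)), left_nodes))
  eps <- 1e-6
  w <- c(pmax(1 + eps - (support[from] + support[to]) / 2, eps),
         rep(eps, length(top_nodes) + length(left_nodes)))
  g <- igraph::graph_from_edgelist(edge_list, directed = FALSE)
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = src, to = snk, weights = w,
                           output = "vpath"))
  vp <- as.integer(sp$vpath[[1L]])
  if (length(vp) < 3L) return(structure(empty, mean_support = NA_real_))
  vp <- vp[vp <= n_nodes]
  curve <- pos[vp, , drop = FALSE]
  structure(unname(curve), mean_support = mean(support[vp]))
}

#' Shape-shifting silhouette extraction
#'
#' Superimposes the filled convex hull on the binary body: the silhouette is
#' the intersection of hull and body with the chest-wall side of the
#' pectoral boundary removed — within every row the curve spans, all pixels
#' at or left of the curve's outermost column are dropped. The result is
#' reduced to its largest 8-connected component, so stray fragments beyond
#' the muscle never survive.
#'
#' @param hull A `hull_image` from [convex_hull()].
#' @param binary Binary body mask (same shape as the hull fill).
#' @param pectoral Pectoral boundary curve from [pectoral_boundary()]; an
#'   empty curve removes nothing.
#' @return Binary silhouette mask.
#' @export
shape_shift <- function(hull, binary, pectoral = matrix(integer(0), 0L, 2L)) {
  if (!inherits(hull, "hull_image"))
    abort_pectoseg("pectoseg_config_error", "`hull` must be a hull_image")
  assert_mask(binary)
  assert_same_shape(hull$filled, binary)
  sil <- hull$filled * binary
  if (nrow(pectoral)) {
    cut <- tapply(pectoral[, 2L], pectoral[, 1L], max)
    rows <- as.integer(names(cut))
    for (i in seq_along(rows))
      sil[rows[i], seq_len(cut[[i]])] <- 0
  }
  if (!any(sil == 1))
    abort_pectoseg("pectoseg_empty_silhouette_error",
                   "silhouette is empty after pectoral removal")
  lab <- label_components(sil, connectivity = 8L)
  sizes <- component_sizes(lab)
  (lab == which.max(sizes)) * 1
}

#' Map the silhouette back to original intensities
#'
#' Pointwise product of silhouette and clean grayscale image: intensities
#' are preserved bit-exactly inside the silhouette and 0 outside, yielding
#' the segmented breast profile.
#'
#' @param sil Binary silhouette mask.
#' @param clean Grayscale image (same shape).
#' @return Grayscale matrix.
#' @export
apply_silhouette <- function(sil, clean) {
  assert_mask(sil)
  if (!is.matrix(clean) || !is.numeric(clean))
    abort_pectoseg("pectoseg_type_error", "`clean` must be a numeric matrix")
  assert_same_shape(sil, clean)
  sil * clean
}
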