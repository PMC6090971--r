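#' Disk structuring element
#'
#' The discrete disk \{(r, c) : r^2 + c^2 <= radius^2\}, symmetric about its
#' center — the shaping element used to seal broken edge boundaries.
#'
#' @param radius Radius in pixels (>= 1).
#' @return A `structuring_element` list with fields `shape`, `radius`,
#'   `footprint` (a (2r+1)x(2r+1) 0/1 matrix) and `offsets` (integer matrix
#'   of (dr, dc) member offsets).
#' @export
disk_se <- function(radius) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L)
    abort_pectoseg("pectoseg_config_error", "`radius` must be an integer >= 1")
  d <- -radius:radius
  fp <- outer(d^2, d^2, "+") <= radius^2
  off <- which(fp, arr.ind = TRUE) - radius - 1L
  structure(list(shape = "disk", radius = radius,
                 footprint = fp * 1, offsets = unname(off)),
            class = "structuring_element")
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Binary dilation
#'
#' Union of translates of the mask by every offset of the structuring
#' element; pixels outside the frame are background. The output always
#' contains the input (disk elements contain the origin).
#'
#' @param mask Binary 0/1 matrix.
#' @param se A [disk_se()].
#' @return Binary matrix of the same shape.
#' @export
mask_dilate <- function(mask, se) {
  assert_mask(mask)
  check_se(se)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se$offsets)))
    out <- pmax(out, shift_mat(mask, se$offsets[i, 1L], se$offsets[i, 2L], 0))
  out
}

#' Binary erosion
#'
#' Keeps the pixels whose entire translated footprint lies in the mask. The
#' footprint is clipped at the image frame (offsets falling outside the
#' image are ignored), so a full mask erodes to a full mask and regions
#' flush with the frame are not eaten from the frame side. Away from the
#' frame this is the dual of dilation:
#' `erode(m) == 1 - dilate(1 - m)`.
#'
#' @inheritParams mask_dilate
#' @return Binary matrix of the same shape.
#' @export
mask_erode <- function(mask, se) {
  assert_mask(mask)
  check_se(se)
  out <- matrix(1, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se$offsets))) {
    # Reflected shift with foreground fill implements footprint clipping.
    out <- pmin(out, shift_mat(mask, -se$offsets[i, 1L], -se$offsets[i, 2L], 1))
  }
  out
}

#' Morphological closing
#'
#' Dilation followed by erosion with the same element. The operation is
#' evaluated on a domain padded by the element radius and cropped back, which
#' makes it exactly the ideal full-plane closing restricted to the image:
#' extensive (output contains input), idempotent, and monotone, including at
#' the image frame. Used to seal the broken edges of the thresholded
#' gradient map into closed boundaries.
#'
#' @inheritParams mask_dilate
#' @return Binary matrix of the same shape.
#' @examples
#' m <- matrix(0, 9, 9); m[3, 2:8] <- 1; m[6, 2:8] <- 1
#' sum(mask_close(m, disk_se(2))) > sum(m)  # the 2-px gap is bridged
#' @export
mask_close <- function(mask, se) {
  assert_mask(mask)
  check_se(se)
  r <- se$radius
  nr <- nrow(mask); nc <- ncol(mask)
  big <- matrix(0, nr + 2L * r, nc + 2L * r)
  big[r + seq_len(nr), r + seq_len(nc)] <- mask
  big <- mask_dilate(big, se)
  # Plain (unclipped) erosion on the padded domain: complement-dilate dual.
  big <- 1 - mask_dilate(1 - big, se)
  big[r + seq_len(nr), r + seq_len(nc)]
}

check_se <- function(se) {
  if (!inherits(se, "structuring_element"))
    abort_pectoseg("pectoseg_config_error",
                   "`se` must be a structuring_element from disk_se()")
  invisible(se)
}
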