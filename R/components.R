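# Connected-component labeling. EBImage::bwlabel() is 4-connected; the
# pipeline's conventions are 8-connected throughout, so 4-labels that touch
# diagonally are merged through an igraph components pass over the label
# adjacency graph.

#' Label connected components of a binary mask
#'
#' @param mask Binary 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape; 0 is background, components are
#'   numbered from 1 with no gaps.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  if (!connectivity %in% c(4L, 8L))
    abort_pectoseg("pectoseg_config_error", "`connectivity` must be 4 or 8")
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # Diagonal neighbor label pairs (down-right and down-left shifts).
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]
    a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
    if (nrow(pairs)) {
      g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(pairs[, 1]),
                   to = as.character(pairs[, 2])),
        directed = FALSE,
        vertices = data.frame(name = as.character(seq_len(nlab))))
      memb <- igraph::components(g)$membership
      remap <- integer(nlab)
      remap[as.integer(names(memb))] <- as.integer(memb)
      fg <- lab > 0L
      lab[fg] <- remap[lab[fg]]
    }
  }
  # Renumber 1..k in first-appearance order for determinism.
  ids <- unique(lab[lab > 0L])
  if (length(ids)) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    fg <- lab > 0L
    lab[fg] <- remap[lab[fg]]
  }
  lab
}

#' @noRd
component_sizes <- function(lab) {
  fg <- lab[lab > 0L]
  if (!length(fg)) return(integer(0))
  tabulate(fg)
}
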