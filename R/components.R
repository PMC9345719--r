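#' Connected-component labeling and hole filling
#'
#' `label_components()` labels the foreground of a binary mask with
#' 8-connectivity (default) or 4-connectivity. Labels are assigned in
#' row-major order of each component's first pixel, so label 1 belongs to the
#' component whose top-left pixel is lexicographically smallest in
#' `(row, col)` — this is the documented tie-break used when selecting the
#' largest component.
#'
#' `fill_holes()` sets to foreground every background region not connected
#' (4-connectivity) to the image border; on a CT body mask this pulls gas and
#' other dark internal structures into the body.
#'
#' @param mask a binary mask.
#' @param connectivity 8 (default) or 4.
#' @return `label_components()`: a list with `labels` (integer matrix, 0 =
#'   background), `sizes` (pixel counts per label) and `n` (component count).
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask <- as_binary_mask(mask)
  if (!connectivity %in% c(4L, 8L)) {
    stop_validation("connectivity must be 4 or 8")
  }
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask == 1L)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0L) {
    return(list(labels = labels, sizes = integer(0), n = 0L))
  }
  idm <- matrix(0L, nr, nc)
  idm[fg] <- seq_along(fg)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  efrom <- integer(0); eto <- integer(0)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0L) seq_len(nc - dc) else seq.int(1L - dc, nc)
    a <- idm[r1, c1, drop = FALSE]
    b <- idm[r1 + dr, c1 + dc, drop = FALSE]
    both <- a > 0L & b > 0L
    efrom <- c(efrom, a[both]); eto <- c(eto, b[both])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(efrom)) {
    g <- igraph::add_edges(g, rbind(efrom, eto))
  }
  memb <- igraph::components(g)$membership
  # relabel so that labels follow row-major order of first appearance
  rr <- (fg - 1L) %% nr + 1L
  cc <- (fg - 1L) %/% nr + 1L
  ord <- order(rr, cc)
  relab <- integer(max(memb))
  nxt <- 0L
  for (i in ord) {
    m <- memb[i]
    if (relab[m] == 0L) { nxt <- nxt + 1L; relab[m] <- nxt }
  }
  lab <- relab[memb]
  labels[fg] <- lab
  list(labels = labels, sizes = tabulate(lab, nxt), n = nxt)
}

#' @rdname label_components
#' @export
fill_holes <- function(mask) {
  mask <- as_binary_mask(mask)
  bg <- as_binary_mask(mask == 0L)
  comp <- label_components(bg, connectivity = 4L)
  lab <- comp$labels
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0L]
  hole <- lab > 0L & !(lab %in% border_labels)
  out <- mask
  out[hole] <- 1L
  out
}

# Internal: mask of the largest component; ties broken by smallest label,
# i.e. smallest row-major top-left pixel (see label_components()).
largest_component <- function(mask, connectivity = 8L) {
  comp <- label_components(mask, connectivity)
  if (comp$n == 0L) stop_degenerate("mask has no foreground component")
  best <- which(comp$sizes == max(comp$sizes))[1L]
  as_binary_mask(comp$labels == best)
}
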