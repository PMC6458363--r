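#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` over OTUs: 0 for identical
#' count vectors, 1 for disjoint supports. A pair of all-zero samples is
#' assigned 0 by convention. This is the beta-diversity metric used by the
#' PERMANOVA, NMDS and Mantel-correlogram stages.
#'
#' @param table An `otu_tbl` (or a numeric sample-by-OTU matrix with
#'   rownames).
#' @return A [stats::dist] object labelled with sample ids, values in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  m <- if (is_otu_tbl(table)) as_count_matrix(table) else as.matrix(table)
  if (nrow(m) < 2) abort("need at least two samples")
  storage.mode(m) <- "double"
  num <- dist(m, method = "manhattan")          # sum |x - y|
  tot <- rowSums(m)
  den <- as.dist(outer(tot, tot, "+"))
  out <- num / den
  out[den == 0] <- 0
  attr(out, "method") <- "bray_curtis"
  out
}

# coerce a dist or symmetric matrix to dist with labels
as_dist_checked <- function(d, what = "distance matrix") {
  if (inherits(d, "dist")) return(d)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) abort(paste(what, "must be square"))
  stats::as.dist(m)
}
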