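#' Spatial distances between samples along planting lines
#'
#' Samples sit along two planting lines (sampling sets) at fixed intervals;
#' the spatial distance between two samples of the same set is
#' `|position difference| * spacing` metres. Pairs from different sets are
#' `NA` — the lines are separate transects and cross-line geometry is not
#' modelled — and such pairs are excluded from correlogram analyses.
#'
#' @param meta Metadata tibble with `sample_id`, `sampling_set`, `position`.
#' @param spacing Distance between adjacent positions in metres
#'   (default 0.30).
#' @return A [stats::dist] labelled with sample ids, `NA` across sets.
#' @export
spatial_distances <- function(meta, spacing = 0.30) {
  pos <- meta$position
  set <- meta$sampling_set
  m <- abs(outer(pos, pos, "-")) * spacing
  m[outer(set, set, "!=")] <- NA_real_
  rownames(m) <- colnames(m) <- meta$sample_id
  stats::as.dist(m)
}

#' Mantel correlogram
#'
#' Bins pairwise spatial distances into classes (equal-width; class count
#' by Sturges' rule when `n_classes` is `NULL`) and computes, for each
#' class, a Mantel statistic between the community dissimilarities and the
#' class membership indicator. The sign convention is ecological: positive
#' `r` at a class means samples in that distance class are *more similar*
#' than average (positive spatial autocorrelation). Per-class significance
#' comes from jointly permuting the rows/columns of the community matrix;
#' p-values are corrected progressively (Holm over classes `1..k` for class
#' `k`). Pairs with `NA` spatial distance (e.g. across sampling sets) are
#' excluded throughout; classes with fewer than 2 pairs are dropped with a
#' warning.
#'
#' @param d_comm Community dissimilarity [stats::dist] (e.g.
#'   [bray_curtis()]).
#' @param d_space Spatial [stats::dist] over the same samples (e.g.
#'   [spatial_distances()]); may contain `NA`.
#' @param n_classes Number of distance classes, or `NULL` for Sturges.
#' @param n_perm Permutations per class (default 999).
#' @param seed Integer seed.
#' @return An `rz_mantel` object; `tidy()` gives one row per class with
#'   `class`, `d_center`, `n_pairs`, `r`, `p`, `p_corr`.
#' @export
mantel_correlogram <- function(d_comm, d_space, n_classes = NULL,
                               n_perm = 999, seed = 1) {
  d_comm <- as_dist_checked(d_comm)
  d_space <- as_dist_checked(d_space)
  n <- attr(d_comm, "Size")
  if (attr(d_space, "Size") != n) abort("sample sets do not match")
  ids_c <- attr(d_comm, "Labels"); ids_s <- attr(d_space, "Labels")
  if (!is.null(ids_c) && !is.null(ids_s) && !identical(ids_c, ids_s)) {
    if (!setequal(ids_c, ids_s)) abort("sample sets do not match")
    ds <- as.matrix(d_space)[ids_c, ids_c]
    d_space <- stats::as.dist(ds)
  }

  dc <- as.vector(d_comm)
  dsv <- as.vector(d_space)
  valid <- !is.na(dsv)
  if (sum(valid) < 2) abort("no valid (non-NA) spatial pairs")

  if (is.null(n_classes)) n_classes <- ceiling(log2(sum(valid)) + 1)
  rng <- range(dsv[valid])
  breaks <- seq(rng[1], rng[2], length.out = n_classes + 1)
  cls <- cut(dsv, breaks = breaks, include.lowest = TRUE, labels = FALSE)

  keep <- which(tabulate(cls[valid], nbins = n_classes) >= 2)
  if (length(keep) < n_classes) {
    warn(sprintf("dropping %d distance class(es) with fewer than 2 pairs",
                 n_classes - length(keep)))
  }

  # positive r = within-class pairs more similar than average
  class_r <- function(dcv, class_id) {
    ind <- as.numeric(valid & !is.na(cls) & cls == class_id)
    -cor(dcv[valid], ind[valid])
  }
  r_obs <- vapply(keep, function(k) class_r(dc, k), numeric(1))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  mc <- as.matrix(d_comm)
  count <- numeric(length(keep))
  for (t in seq_len(n_perm)) {
    p <- sample.int(n)
    dcp <- as.vector(stats::as.dist(mc[p, p]))
    rp <- vapply(keep, function(k) class_r(dcp, k), numeric(1))
    count <- count + (abs(rp) >= abs(r_obs) - 1e-12)
  }
  p_val <- (1 + count) / (n_perm + 1)
  p_corr <- vapply(seq_along(p_val), function(k) {
    p.adjust(p_val[seq_len(k)], method = "holm")[k]
  }, numeric(1))

  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  structure(list(
    table = tibble(class = keep, d_center = centers[keep],
                   n_pairs = tabulate(cls[valid], nbins = n_classes)[keep],
                   r = r_obs, p = p_val, p_corr = p_corr),
    breaks = breaks, n_perm = n_perm, seed = seed),
    class = "rz_mantel")
}

#' @export
print.rz_mantel <- function(x, ...) {
  cat(sprintf("Mantel correlogram (%d classes, %d permutations)\n",
              nrow(x$table), x$n_perm))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a Mantel correlogram
#'
#' @param x An `rz_mantel` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rz_mantel <- function(x, ...) x$table

#' @rdname tidy.rz_mantel
#' @exportS3Method generics::glance
glance.rz_mantel <- function(x, ...) {
  tibble(n_classes = nrow(x$table), n_perm = x$n_perm,
         min_p_corr = min(x$table$p_corr))
}
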