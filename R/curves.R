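#' Per-sample rarefaction curves (analytic)
#'
#' Expected OTU richness of each sample when subsampled without replacement
#' to a given depth, computed from the exact hypergeometric expectation
#' `E[S(d)] = sum_i (1 - C(N - n_i, d) / C(N, d))` — no resampling noise.
#' Depths exceeding a sample's total are omitted for that sample; at
#' `depth = total` the curve reaches the observed richness.
#'
#' @param table An `otu_tbl`.
#' @param depths Integer vector of subsampling depths; default is 20 values
#'   spread from 1 to the largest sample total.
#' @return A tibble with columns `sample_id`, `depth`, `richness`.
#' @export
rarefaction_curve <- function(table, depths = NULL) {
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  if (is.null(depths)) {
    depths <- unique(round(seq(1, max(totals), length.out = 20)))
  }
  purrr::map_dfr(seq_len(nrow(m)), function(s) {
    n_tot <- totals[s]
    dd <- depths[depths <= n_tot]
    counts <- m[s, ]
    counts <- counts[counts > 0]
    rich <- vapply(dd, function(d) {
      sum(1 - exp(lchoose(n_tot - counts, d) - lchoose(n_tot, d)))
    }, numeric(1))
    tibble(sample_id = rownames(m)[s], depth = unname(dd),
           richness = unname(rich))
  })
}

#' Sample-based OTU accumulation curve
#'
#' Mean (and s.d. of) cumulative OTU count as samples are added in random
#' order, over `reps` random orderings.
#'
#' @param table An `otu_tbl`.
#' @param reps Number of random sample orderings (default 100).
#' @param seed Integer seed.
#' @return A tibble with columns `n_samples`, `richness`, `sd`.
#' @export
accumulation_curve <- function(table, reps = 100, seed = 1) {
  m <- as_count_matrix(table) > 0
  n <- nrow(m)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  acc <- matrix(0, reps, n)
  for (r in seq_len(reps)) {
    seen <- rep(FALSE, ncol(m))
    for (i in seq_along(ord <- sample.int(n))) {
      seen <- seen | m[ord[i], ]
      acc[r, i] <- sum(seen)
    }
  }
  tibble(n_samples = seq_len(n),
         richness = colMeans(acc),
         sd = apply(acc, 2, sd))
}
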