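#' Observed per-state mean read counts
#'
#' For every OTU `i` and plant state `j`, the arithmetic mean of the OTU's
#' read count over the samples in that state — the observed statistic the
#' preference index standardizes.
#'
#' @param table An `otu_tbl` (normally the rarefied matrix).
#' @param meta Sample metadata covering every sample in `table` (see
#'   [read_sample_metadata()]).
#' @return A tibble with columns `otu_id`, `state`, `n_observed`.
#' @export
observed_state_means <- function(table, meta) {
  meta <- align_metadata(table, meta)
  states <- levels(meta$plant_state)
  empty <- setdiff(states, unique(as.character(meta$plant_state)))
  if (length(empty)) {
    abort(paste0("plant state(s) with zero samples: ",
                 paste(empty, collapse = ", ")))
  }
  m <- as_count_matrix(table)
  means <- vapply(states, function(st) {
    colMeans(m[meta$plant_state == st, , drop = FALSE])
  }, numeric(ncol(m)))
  tibble(otu_id = rep(colnames(m), times = length(states)),
         state = factor(rep(states, each = ncol(m)), levels = states),
         n_observed = as.vector(means))
}

#' Permutation null distribution of per-state mean counts
#'
#' Builds the randomization null for the preference index: plant-state
#' labels are shuffled jointly across all samples (`n_perm` times, counts
#' untouched) and, for every (OTU, state) pair, the mean and standard
#' deviation of the per-state mean count across permutations are recorded,
#' together with the number of permutations whose mean deviates from the
#' null mean at least as far as the observed mean (the two-sided empirical-p
#' numerator). The null s.d. uses the population denominator, so Monte-Carlo
#' values converge to exact enumeration over all label assignments.
#'
#' Samples are processed in `sample_id` order internally, so results do not
#' depend on the row order of `table`. With `stratify_by_set = TRUE` labels
#' are shuffled only within each sampling set — a sensitivity analysis for
#' spatially structured designs; the default is the unrestricted shuffle.
#'
#' @inheritParams observed_state_means
#' @param n_perm Number of label permutations (default 100000).
#' @param seed Integer seed; results are reproducible given `(seed, n_perm)`.
#' @param stratify_by_set Shuffle labels within sampling sets only.
#' @return A tibble with columns `otu_id`, `state`, `n_observed`,
#'   `null_mean`, `null_sd`, `n_exceed`, `n_perm`.
#' @export
permutation_null <- function(table, meta, n_perm = 100000, seed = 1,
                             stratify_by_set = FALSE) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  meta <- align_metadata(table, meta)
  ord <- order(sample_ids(table))
  m <- as_count_matrix(table)[ord, , drop = FALSE]
  meta <- meta[ord, , drop = FALSE]
  states <- levels(meta$plant_state)
  empty <- setdiff(states, unique(as.character(meta$plant_state)))
  if (length(empty)) {
    abort(paste0("plant state(s) with zero samples: ",
                 paste(empty, collapse = ", ")))
  }
  state_code <- as.integer(meta$plant_state) - 1L
  strata <- if (stratify_by_set) as.integer(meta$sampling_set) - 1L
            else integer(nrow(meta))
  obs <- vapply(states, function(st) {
    colMeans(m[meta$plant_state == st, , drop = FALSE])
  }, numeric(ncol(m)))
  obs <- matrix(obs, ncol = length(states))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  k <- perm_null_kernel(t(m), state_code, obs, strata,
                        length(states), as.integer(n_perm))

  tibble(otu_id = rep(colnames(m), times = length(states)),
         state = factor(rep(states, each = ncol(m)), levels = states),
         n_observed = as.vector(obs),
         null_mean = as.vector(k$null_mean),
         null_sd = as.vector(k$null_sd),
         n_exceed = as.vector(k$exceed),
         n_perm = as.integer(n_perm))
}

#' Standardized preference scores from observed and null summaries
#'
#' The preference of OTU `i` for plant state `j` is the z-score of its
#' observed per-state mean against the label-shuffling null:
#' `(n_observed - null_mean) / null_sd`. Pairs with `null_sd = 0` (an OTU
#' constant across samples, so label-invariant) are flagged `degenerate` and
#' assigned preference 0 and empirical p 1 — they can never pass the screen.
#' The two-sided empirical p uses the add-one estimator
#' `(1 + n_exceed) / (n_perm + 1)`, so it is never zero.
#'
#' @param observed Tibble from [observed_state_means()], or `NULL` when
#'   `null` already carries `n_observed` (as [permutation_null()] output
#'   does).
#' @param null Tibble from [permutation_null()].
#' @return A `preference_tbl` tibble with columns `otu_id`, `state`,
#'   `n_observed`, `null_mean`, `null_sd`, `preference`, `p_emp`, `q`
#'   (`NA` until [fdr_adjust()]), `n_perm`, `degenerate`.
#' @export
preference_scores <- function(observed = NULL, null) {
  res <- if (is.null(observed) && "n_observed" %in% names(null)) null
         else left_join(observed, select(null, -"n_observed"),
                        by = c("otu_id", "state"))
  if (anyNA(res$null_mean)) abort("observed and null tables do not align")
  res <- mutate(res,
    degenerate = .data$null_sd == 0,
    preference = ifelse(.data$degenerate, 0,
                        (.data$n_observed - .data$null_mean) /
                          ifelse(.data$degenerate, 1, .data$null_sd)),
    p_emp = ifelse(.data$degenerate, 1,
                   (1 + .data$n_exceed) / (.data$n_perm + 1)),
    q = NA_real_)
  out <- select(res, "otu_id", "state", "n_observed", "null_mean",
                "null_sd", "preference", "p_emp", "q", "n_perm",
                "degenerate")
  class(out) <- c("preference_tbl", class(out))
  out
}

#' Benjamini-Hochberg adjustment of empirical permutation p-values
#'
#' Adjusts `p_emp` across all (OTU, state) pairs of one dataset (one marker
#' x compartment matrix), filling the `q` column. BH guarantees
#' `q >= p_emp` and monotonicity in the p-value ranking.
#'
#' @param results A `preference_tbl` from [preference_scores()].
#' @return The same tibble with `q` filled.
#' @export
fdr_adjust <- function(results) {
  results$q <- p.adjust(results$p_emp, method = "BH")
  results
}

#' Screen for strongly preferential OTUs
#'
#' Keeps (OTU, state) pairs whose preference score is at least `z_min`
#' (inclusive; the conventional cutoff of 3 corresponds to FDR < 0.05 under
#' permutation-calibrated screens, which [generate_community()]-based
#' simulation can verify for a given design). Results are grouped by state
#' and sorted by descending preference within state.
#'
#' @param results A `preference_tbl`.
#' @param z_min Minimum preference score (default 3, must be positive).
#' @return The filtered, sorted `preference_tbl`.
#' @export
screen_preferential <- function(results, z_min = 3) {
  if (z_min <= 0) abort("z_min must be positive")
  out <- arrange(filter(results, .data$preference >= z_min),
                 .data$state, desc(.data$preference))
  class(out) <- unique(c("preference_tbl", class(out)))
  out
}

#' Full preference screen on one count table
#'
#' Convenience pipeline: observed per-state means, label-shuffling
#' permutation null, standardized preference scores, BH-adjusted empirical
#' p-values. Returns the complete score table; apply [screen_preferential()]
#' for the shortlist.
#'
#' @inheritParams permutation_null
#' @return A `preference_tbl` covering every (OTU, state) pair.
#' @export
preference_screen <- function(table, meta, n_perm = 100000, seed = 1,
                              stratify_by_set = FALSE) {
  null <- permutation_null(table, meta, n_perm = n_perm, seed = seed,
                           stratify_by_set = stratify_by_set)
  fdr_adjust(preference_scores(null = null))
}
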