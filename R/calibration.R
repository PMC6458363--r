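#' Replicate-level calibration of the preference screen
#'
#' Runs the whole screen against communities with known ground truth:
#' each replicate draws a fresh community (ranked log-normal baseline,
#' Dirichlet-multinomial counts at fixed depth) with a fraction of OTUs
#' planted as fold-enriched in one state via [plant_preferential()], runs
#' the permutation screen, and tallies, per (OTU, state) call passing
#' `z_min`, whether the call matches a planted effect. Pooling the
#' replicates gives the empirical false discovery rate of the `z >= z_min`
#' rule and the sensitivity for planted effects — the simulation evidence
#' behind treating the conventional cutoff of 3 as an FDR < 0.05 screen.
#'
#' Replicate `r` uses seed `base_seed + r - 1` for its community and a
#' seed derived from that for its permutations, so the whole experiment is
#' reproducible from `base_seed`.
#'
#' @param n_reps Number of replicate communities (default 50).
#' @param n_otus OTUs per community (default 150).
#' @param n_per_state Samples per state (default 97, 19, 15).
#' @param planted_frac Fraction of OTUs planted (default 0.1).
#' @param fold Planted fold enrichment (default 8).
#' @param depth Fixed read depth per sample (default 1000).
#' @param n_perm Permutations per replicate screen (default 20000).
#' @param z_min Preference cutoff (default 3).
#' @param base_seed Seed of the first replicate (default 1).
#' @return A list: `calls` (tibble of all calls with `replicate`, `otu_id`,
#'   `state`, `preference`, `true_positive`), `planted` (tibble of all
#'   planted effects with baseline abundance and a `detected` flag),
#'   `fdr` (pooled empirical FDR) and `n_calls`.
#' @export
screen_calibration <- function(n_reps = 50, n_otus = 150,
                               n_per_state = c(97, 19, 15),
                               planted_frac = 0.1, fold = 8,
                               depth = 1000, n_perm = 20000, z_min = 3,
                               base_seed = 1) {
  n_planted <- round(planted_frac * n_otus)
  calls <- list(); planted <- list()
  for (r in seq_len(n_reps)) {
    seed_r <- base_seed + r - 1
    pref_spec <- if (n_planted > 0) {
      plant_preferential(n_planted, n_otus, fold = fold)
    }
    # planted state effects only: spatial field and co-abundance graph off,
    # so unplanted OTUs are label-exchangeable by construction
    b <- generate_community(n_per_state = n_per_state, n_otus = n_otus,
                            preferential = pref_spec, depth = depth,
                            spatial_rho = 0, spatial_scale = 0,
                            graph_edges = NULL, seed = seed_r)
    res <- preference_screen(b$table, b$metadata, n_perm = n_perm,
                             seed = stream_seed(seed_r, "screen"))
    truth_key <- paste(b$truth$preferential$otu_id,
                       b$truth$preferential$state)
    hit <- filter(res, !.data$degenerate, .data$preference >= z_min)
    calls[[r]] <- tibble(replicate = r, otu_id = hit$otu_id,
                         state = as.character(hit$state),
                         preference = hit$preference,
                         true_positive = paste(hit$otu_id,
                                               hit$state) %in% truth_key)
    planted[[r]] <- mutate(b$truth$preferential,
                           replicate = r,
                           baseline = unname(
                             b$truth$baseline[b$truth$preferential$otu_id]),
                           detected = paste(.data$otu_id, .data$state) %in%
                             paste(calls[[r]]$otu_id, calls[[r]]$state))
  }
  calls <- bind_rows(calls)
  planted <- bind_rows(planted)
  list(calls = calls, planted = planted,
       fdr = if (nrow(calls)) mean(!calls$true_positive) else 0,
       n_calls = nrow(calls))
}
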