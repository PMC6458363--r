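test_that("observed state means are per-state arithmetic means of counts", {
  tab <- tiny_table(matrix(c(10L, 10L, 0L, 0L), 4, 1),
                    sample_ids = sprintf("s%d", 1:4))
  meta <- tiny_meta(sprintf("s%d", 1:4),
                    factor(c("green", "green", "no_leaf", "no_leaf"),
                           levels = c("green", "no_leaf")))
  obs <- observed_state_means(tab, meta)
  expect_equal(obs$n_observed[obs$state == "green"], 10)
  expect_equal(obs$n_observed[obs$state == "no_leaf"], 0)

  # all-zero OTU -> zero means everywhere
  tab0 <- tiny_table(cbind(matrix(c(10L, 10L, 0L, 0L), 4, 1), 0L),
                     sample_ids = sprintf("s%d", 1:4))
  obs0 <- observed_state_means(tab0, meta)
  expect_true(all(obs0$n_observed[obs0$otu_id == "P_0002"] == 0))

  # brute-force recount on a random table with the three field states
  tabr <- random_table(30, 12, seed = 4)
  metar <- tiny_meta(sample_ids(tabr),
                     factor(rep(c("green", "yellow", "no_leaf"), length.out = 30),
                            levels = c("green", "yellow", "no_leaf")))
  obsr <- observed_state_means(tabr, metar)
  mr <- as_count_matrix(tabr)
  for (st in levels(metar$plant_state)) {
    want <- colMeans(mr[as.character(metar$plant_state) == st, , drop = FALSE])
    got <- obsr$n_observed[obsr$state == st]
    expect_equal(got, unname(want[obsr$otu_id[obsr$state == st]]))
  }

  # a declared state with zero samples is an error
  meta_empty <- tiny_meta(sprintf("s%d", 1:4),
                          factor(c("green", "green", "no_leaf", "no_leaf"),
                                 levels = c("green", "yellow", "no_leaf")))
  expect_error(observed_state_means(tab, meta_empty), "zero samples")
})

test_that("permutation null converges to the exact enumeration values", {
  # 4 samples, states (A,A,B,B), counts (10,10,0,0): over all C(4,2)=6
  # label assignments the state-A mean has mean 5 and sd sqrt(50/6),
  # giving preference sqrt(3)
  tab <- tiny_table(matrix(c(10L, 10L, 0L, 0L), 4, 1),
                    sample_ids = sprintf("s%d", 1:4))
  meta <- tiny_meta(sprintf("s%d", 1:4),
                    factor(c("green", "green", "no_leaf", "no_leaf"),
                           levels = c("green", "no_leaf")))
  null <- permutation_null(tab, meta, n_perm = 200000, seed = 1)
  g <- null[null$state == "green", ]
  expect_lt(abs(g$null_mean - 5), 0.03)
  expect_lt(abs(g$null_sd - sqrt(50 / 6)), 0.03)
  res <- preference_scores(null = null)
  expect_lt(abs(res$preference[res$state == "green"] - sqrt(3)), 0.03)

  # convergence: the mean error over independent seeds shrinks with n_perm
  mean_err <- function(np) {
    mean(vapply(1:5, function(sd_i) {
      nl <- permutation_null(tab, meta, n_perm = np, seed = sd_i)
      abs(nl$null_sd[nl$state == "green"] - sqrt(50 / 6))
    }, numeric(1)))
  }
  expect_lt(mean_err(20000), mean_err(100))
})

test_that("constant OTUs are degenerate and never pass the screen", {
  tab <- tiny_table(matrix(7L, 6, 1), sample_ids = sprintf("s%d", 1:6))
  meta <- tiny_meta(sprintf("s%d", 1:6),
                    factor(rep(c("green", "no_leaf"), 3),
                           levels = c("green", "no_leaf")))
  res <- preference_screen(tab, meta, n_perm = 500, seed = 1)
  expect_true(all(res$degenerate))
  expect_true(all(res$preference == 0))
  expect_true(all(res$p_emp == 1))
  expect_identical(nrow(screen_preferential(res)), 0L)
})

test_that("results are invariant to sample order and reproducible by seed", {
  tab <- random_table(24, 15, seed = 8)
  meta <- tiny_meta(sample_ids(tab),
                    factor(rep(c("green", "yellow", "no_leaf"), each = 8),
                           levels = c("green", "yellow", "no_leaf")))
  r1 <- preference_screen(tab, meta, n_perm = 2000, seed = 5)
  perm <- sample(seq_len(24))
  tab_shuf <- otu_table(tibble::as_tibble(tab)[perm, ], "16S", "root")
  r2 <- preference_screen(tab_shuf, meta, n_perm = 2000, seed = 5)
  expect_equal(r1, r2)
  r3 <- preference_screen(tab, meta, n_perm = 2000, seed = 5)
  expect_identical(r1$null_mean, r3$null_mean)
})

test_that("monte-carlo preference scores are stable across seeds", {
  bundle <- generate_community(n_per_state = c(20, 12, 12), n_otus = 200,
                               depth = 500, seed = 31)
  a <- preference_screen(bundle$table, bundle$metadata, n_perm = 100000,
                         seed = 1)
  b <- preference_screen(bundle$table, bundle$metadata, n_perm = 100000,
                         seed = 2)
  keep <- !a$degenerate & !b$degenerate
  expect_lt(max(abs(a$preference[keep] - b$preference[keep])), 0.05)
})

test_that("empirical p and BH q respect their contracts", {
  tab <- random_table(18, 10, seed = 13)
  meta <- tiny_meta(sample_ids(tab),
                    factor(rep(c("green", "yellow", "no_leaf"), 6),
                           levels = c("green", "yellow", "no_leaf")))
  res <- preference_screen(tab, meta, n_perm = 999, seed = 2)
  expect_true(all(res$p_emp >= 1 / 1000 & res$p_emp <= 1))
  expect_true(all(res$q >= res$p_emp - 1e-12))
  expect_true(all(res$q <= 1))

  # hand BH example and the single-test identity
  fake <- res[1:4, ]
  fake$p_emp <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(fdr_adjust(fake)$q, rep(0.04, 4))
  single <- res[1, ]
  single$p_emp <- 0.2
  expect_equal(fdr_adjust(single)$q, 0.2)
})

test_that("screening is inclusive at the threshold and sorted within state", {
  tab <- random_table(18, 10, seed = 13)
  meta <- tiny_meta(sample_ids(tab),
                    factor(rep(c("green", "yellow", "no_leaf"), 6),
                           levels = c("green", "yellow", "no_leaf")))
  res <- preference_screen(tab, meta, n_perm = 200, seed = 2)
  res$preference[1:3] <- c(3.0, 2.999, 5)
  hits <- screen_preferential(res, z_min = 3)
  expect_true(all(hits$preference >= 3))
  expect_true(res$otu_id[1] %in% hits$otu_id)    # exactly 3.0 kept
  for (st in unique(hits$state)) {
    expect_false(is.unsorted(rev(hits$preference[hits$state == st])))
  }
  expect_error(screen_preferential(res, z_min = 0), "positive")
})

test_that("a planted 8-fold enriched OTU is recovered for its planted state", {
  pref <- tibble::tibble(otu = 6L, state = "no_leaf", fold = 8)
  bundle <- generate_community(n_per_state = c(40, 12, 12), n_otus = 60,
                               preferential = pref, depth = 1000, seed = 17)
  res <- preference_screen(bundle$table, bundle$metadata, n_perm = 5000,
                           seed = 4)
  hits <- screen_preferential(res)
  planted <- bundle$truth$preferential
  expect_true(any(hits$otu_id == planted$otu_id &
                    as.character(hits$state) == planted$state))
})

test_that("stratified shuffling restricts permutations to sampling sets", {
  # an OTU perfectly aligned with sampling set: under stratified shuffling
  # its per-state null collapses far less than under free shuffling
  counts <- matrix(c(rep(20L, 10), rep(0L, 10)), 20, 1)
  tab <- tiny_table(counts, sample_ids = sprintf("s%02d", 1:20))
  meta <- tiny_meta(sample_ids(tab),
                    factor(rep(c("green", "no_leaf"), 10),
                           levels = c("green", "no_leaf")),
                    sets = rep(c(1L, 2L), each = 10))
  free <- permutation_null(tab, meta, n_perm = 3000, seed = 1)
  strat <- permutation_null(tab, meta, n_perm = 3000, seed = 1,
                            stratify_by_set = TRUE)
  expect_false(isTRUE(all.equal(free$null_sd, strat$null_sd)))
})
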