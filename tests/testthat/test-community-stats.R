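test_that("bray-curtis matches its formula and a double-loop oracle", {
  tab <- tiny_table(rbind(c(5L, 5L, 0L), c(0L, 5L, 5L), c(5L, 5L, 0L),
                          c(9L, 0L, 0L), c(0L, 0L, 4L)))
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["s1", "s2"], 0.5)          # 10/20
  expect_equal(d["s1", "s3"], 0)            # identical
  expect_equal(d["s4", "s5"], 1)            # disjoint supports
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))

  # naive double loop on a random 10 x 20 table
  tabr <- random_table(10, 20, seed = 3)
  m <- as_count_matrix(tabr)
  got <- as.matrix(bray_curtis(tabr))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(got[i, j],
                 sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ]))
  }
  expect_true(all(got >= 0 & got <= 1))

  # all-zero pair is 0 by convention
  tab0 <- tiny_table(rbind(c(0L, 0L), c(0L, 0L), c(1L, 2L)))
  expect_equal(as.matrix(bray_curtis(tab0))["s1", "s2"], 0)
})

test_that("permanova conserves SS and reproduces vegan adonis2 exactly", {
  skip_if_not_installed("vegan")
  bundle <- generate_community(n_per_state = c(20, 8, 6), n_otus = 40,
                               depth = 1000, seed = 7)
  d <- bray_curtis(bundle$table)
  fit <- permanova(d, bundle$metadata, c("sampling_set", "plant_state"),
                   n_perm = 500, seed = 2)
  tb <- tidy(fit)
  expect_lt(abs(sum(tb$ss) - fit$ss_total) / fit$ss_total, 1e-8)

  ref <- vegan::adonis2(d ~ sampling_set + plant_state,
                        data = as.data.frame(bundle$metadata),
                        permutations = 99, by = "terms")
  expect_equal(fit$table$ss, ref$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(fit$table$f, ref$F[1:2], tolerance = 1e-10)
  expect_equal(fit$residual$ss, ref$SumOfSqs[3], tolerance = 1e-10)

  # continuous covariate route (dry mass) agrees too
  fit2 <- permanova(d, bundle$metadata, c("sampling_set", "dry_mass"),
                    n_perm = 99, seed = 2)
  ref2 <- vegan::adonis2(d ~ sampling_set + dry_mass,
                         data = as.data.frame(bundle$metadata),
                         permutations = 99, by = "terms")
  expect_equal(fit2$table$f, ref2$F[1:2], tolerance = 1e-10)
})

test_that("permanova detects separated clusters and matches exact enumeration", {
  set.seed(9)
  x <- rbind(matrix(rnorm(10 * 4), 10, 4),
             matrix(rnorm(10 * 4, mean = 6), 10, 4))
  rownames(x) <- sprintf("s%02d", 1:20)
  d <- dist(x)
  meta <- tiny_meta(rownames(x), rep(c("green", "no_leaf"), each = 10))
  fit <- permanova(d, meta, "plant_state", n_perm = 999, seed = 1)
  expect_equal(fit$table$p, 1 / 1000)
  expect_gt(fit$table$f, 10)

  # n = 6: monte-carlo p converges to exact enumeration over 720 orderings
  set.seed(11)
  x6 <- matrix(rnorm(6 * 3), 6, 3) + rep(c(0, 1.5), each = 3)
  rownames(x6) <- sprintf("s%d", 1:6)
  d6 <- dist(x6)
  meta6 <- tiny_meta(rownames(x6), rep(c("green", "no_leaf"), each = 3))
  ex <- permanova(d6, meta6, "plant_state", exact = TRUE)
  mc <- permanova(d6, meta6, "plant_state", n_perm = 50000, seed = 3)
  expect_lt(abs(ex$table$p - mc$table$p), 0.01)
  expect_identical(ex$n_perm, 720L)
})

test_that("sequential SS depends on term order for collinear designs", {
  set.seed(15)
  n <- 30
  grp <- rep(c("green", "no_leaf"), each = n / 2)
  covar <- ifelse(grp == "green", 0, 3) + rnorm(n)   # collinear with group
  x <- matrix(rnorm(n * 5), n, 5) + covar            # both explain d
  rownames(x) <- sprintf("s%02d", 1:n)
  meta <- tiny_meta(rownames(x), grp)
  meta$covar <- covar
  d <- dist(x)
  f1 <- permanova(d, meta, c("plant_state", "covar"), n_perm = 49, seed = 1)
  f2 <- permanova(d, meta, c("covar", "plant_state"), n_perm = 49, seed = 1)
  ss1 <- f1$table$ss[f1$table$term == "plant_state"]
  ss2 <- f2$table$ss[f2$table$term == "plant_state"]
  expect_gt(abs(ss1 - ss2) / max(ss1, ss2), 0.1)
})

test_that("permanova rejects degenerate designs and drops incomplete samples", {
  tab <- random_table(10, 8, seed = 1)
  d <- bray_curtis(tab)
  meta <- tiny_meta(sample_ids(tab), rep("green", 10))
  expect_error(permanova(d, meta, "plant_state", n_perm = 9),
               "single level")
  meta2 <- tiny_meta(sample_ids(tab), rep(c("green", "no_leaf"), 5),
                     dry_mass = c(NA, NA, runif(8)))
  expect_message(
    fit <- permanova(d, meta2, c("plant_state", "dry_mass"), n_perm = 49),
    "dropping 2")
  expect_identical(fit$n, 8L)
  tiny <- tiny_table(matrix(1:9, 3))
  meta3 <- tiny_meta(sample_ids(tiny), c("green", "no_leaf", "yellow"))
  expect_error(permanova(bray_curtis(tiny), meta3, "plant_state",
                         n_perm = 9), "too few samples")
})

test_that("nmds recovers planted low-dimensional structure", {
  # points on a line embedded from their true distances: near-zero stress
  pos <- seq(0, 10, length.out = 15) + c(0, runif(14, 0, 0.2))
  d <- dist(cbind(pos, 0))
  attr(d, "Labels") <- sprintf("s%02d", 1:15)
  fit <- nmds(d, k = 2, n_starts = 8, seed = 2)
  expect_lt(fit$stress, 0.01)

  # distances generated from an exact 2-D configuration: stress ~ 0 and
  # independent fits agree up to rotation/reflection
  set.seed(4)
  conf <- matrix(rnorm(12 * 2), 12, 2)
  d2 <- dist(conf)
  attr(d2, "Labels") <- sprintf("p%02d", 1:12)
  fa <- nmds(d2, n_starts = 6, seed = 10, tol = 1e-12, max_iter = 2000)
  fb <- nmds(d2, n_starts = 6, seed = 99, tol = 1e-12, max_iter = 2000)
  expect_lt(fa$stress, 1e-4)
  expect_lt(procrustes_error(fa, fb), 1e-4)

  # the stress path never increases within the winning start
  expect_true(all(diff(fa$stress_path) <= 1e-12))
  expect_true(all(diff(fit$stress_path) <= 1e-12))
})

test_that("nmds stress is comparable to vegan metaMDS on real-shaped data", {
  skip_if_not_installed("vegan")
  bundle <- generate_community(n_per_state = c(15, 6, 5), n_otus = 30,
                               depth = 800, seed = 12)
  d <- bray_curtis(bundle$table)
  ours <- nmds(d, n_starts = 10, seed = 1)
  ref <- vegan::monoMDS(d, k = 2)
  expect_lt(ours$stress, ref$stress + 0.02)
  expect_true(ours$stress >= 0 && ours$stress <= 1)
})

test_that("mantel correlogram finds planted short-range similarity", {
  set.seed(6)
  n <- 40
  meta <- tiny_meta(sprintf("s%02d", 1:n), rep("green", n),
                    positions = 1:n)
  dsp <- spatial_distances(meta)
  noise <- matrix(runif(n * n, 0, 1.5), n, n)
  dcm <- stats::as.dist((noise + t(noise)) / 2 + as.matrix(dsp) / 3)
  mc <- mantel_correlogram(dcm, dsp, n_perm = 199, seed = 1)
  tb <- tidy(mc)
  expect_gt(tb$r[1], 0)
  expect_lt(tb$p_corr[1], 0.05)
  expect_true(all(tb$r >= -1 & tb$r <= 1))
})

test_that("mantel correlogram matches vegan and behaves under the null", {
  skip_if_not_installed("vegan")
  set.seed(3)
  n <- 30
  meta <- tiny_meta(sprintf("s%02d", 1:n), rep("green", n))
  dsp <- spatial_distances(meta)
  noise <- matrix(runif(n * n), n, n)
  dcm <- stats::as.dist((noise + t(noise)) / 2 + as.matrix(dsp) / 4)
  ours <- mantel_correlogram(dcm, dsp, n_perm = 99, seed = 1)
  ref <- vegan::mantel.correlog(dcm, XY = cbind(meta$position * 0.3, 0),
                                nperm = 49)
  # compare the short-range classes; at longer range the two
  # implementations bin lattice-tied distances differently at the breaks
  k <- min(4, nrow(ours$table), sum(!is.na(ref$mantel.res[, 3])))
  expect_equal(ours$table$r[1:k], unname(ref$mantel.res[1:k, 3]),
               tolerance = 1e-10)

  # shuffled community labels: no class should be extreme
  set.seed(8)
  perm <- sample(n)
  dshuf <- stats::as.dist(as.matrix(dcm)[perm, perm])
  null_mc <- mantel_correlogram(dshuf, dsp, n_perm = 199, seed = 2)
  expect_gt(min(tidy(null_mc)$p_corr), 0.001)

  # cross-set pairs are excluded via NA distances
  meta2 <- tiny_meta(sprintf("s%02d", 1:n), rep("green", n),
                     sets = rep(c(1L, 2L), each = n / 2),
                     positions = rep(1:(n / 2), 2))
  dsp2 <- spatial_distances(meta2)
  expect_true(anyNA(as.vector(dsp2)))
  expect_s3_class(suppressWarnings(
    mantel_correlogram(dcm, dsp2, n_perm = 49, seed = 1)), "rz_mantel")
})

test_that("rarefaction and accumulation curves obey their boundary identities", {
  tab <- tiny_table(rbind(c(50L, 30L, 15L, 4L, 1L),
                          c(10L, 10L, 0L, 0L, 0L)))
  m <- as_count_matrix(tab)
  cv <- rarefaction_curve(tab, depths = c(1, 20, rowSums(m)[1]))
  # depth 1: expected richness is exactly 1
  expect_equal(cv$richness[cv$depth == 1], c(1, 1))
  # depth = total: observed richness
  expect_equal(cv$richness[cv$sample_id == "s1" & cv$depth == 100], 5)

  # analytic curve matches monte-carlo subsampling
  reps <- 1500
  mc <- vapply(seq_len(reps), function(i) {
    sub <- rarefy(tiny_table(m[1, , drop = FALSE], sample_ids = "s1"),
                  depth = 20, seed = i)
    sum(as_count_matrix(sub) > 0)
  }, numeric(1))
  analytic <- cv$richness[cv$sample_id == "s1" & cv$depth == 20]
  expect_lt(abs(mean(mc) - analytic), 3 * sd(mc) / sqrt(reps))

  acc <- accumulation_curve(tab, reps = 50, seed = 1)
  expect_equal(acc$richness[2], 5)            # all OTUs seen with both samples
  expect_true(!is.unsorted(acc$richness))
})
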