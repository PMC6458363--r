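test_that("clr transform matches its formula and compositional invariance", {
  # constant row -> all zeros
  tab <- tiny_table(matrix(c(4L, 4L, 4L), 1))
  expect_equal(unname(clr_transform(tab)[1, ]), c(0, 0, 0))

  # direct formula on (1, 10, 100) with pseudocount 1
  z <- clr_transform(tiny_table(matrix(c(1L, 10L, 100L), 1)))[1, ]
  lg <- log(c(2, 11, 101))
  expect_equal(unname(z), lg - mean(lg))
  expect_lt(abs(sum(z)), 1e-12)

  # every row sums to zero on random tables
  zr <- clr_transform(random_table(15, 12, seed = 2))
  expect_true(all(abs(rowSums(zr)) < 1e-10))

  # scaling a sample leaves CLR unchanged in the pc -> 0 limit
  x <- matrix(c(3, 7, 20), 1)
  z1 <- clr_transform(x, pseudocount = 1e-9)
  z10 <- clr_transform(x * 10, pseudocount = 1e-9)
  expect_equal(z1, z10, tolerance = 1e-6)
  expect_error(clr_transform(x, pseudocount = 0), "pseudocount")
})

test_that("network path hits its sparse and dense limits", {
  set.seed(20)
  x <- matrix(rnorm(200 * 8), 200, 8)
  colnames(x) <- sprintf("V%02d", 1:8)
  lams <- lambda_path(x)
  path <- fit_network_path(x, method = "mb", lambdas = lams)
  # independent columns, largest lambda: empty graph
  expect_equal(sum(path$adj[[1]]), 0)
  # lambda -> 0 with n >> p: near-complete graph
  dense <- path$adj[[length(lams)]]
  expect_gt(sum(dense[upper.tri(dense)]) / choose(8, 2), 0.9)

  # degenerate (constant) column is a named error
  x_bad <- cbind(x, V99 = 0)
  expect_error(fit_network_path(x_bad, "mb"), "V99")
  expect_error(fit_network_path(x, "mb", lambdas = c(1, 2)), "descending")
})

test_that("oracle-lambda fit recovers a planted chain with F1 >= 0.8", {
  x <- chain_gaussian(300, 20, seed = 2)
  path <- fit_network_path(x, method = "mb")
  truth <- chain_edge_keys(20)
  f1s <- vapply(seq_along(path$lambdas), function(l) {
    a <- path$adj[[l]]
    ij <- which(a & upper.tri(a), arr.ind = TRUE)
    got <- paste(colnames(x)[ij[, 1]], colnames(x)[ij[, 2]], sep = "|")
    tp <- sum(got %in% truth)
    2 * tp / (length(got) + length(truth))
  }, numeric(1))
  expect_gte(max(f1s), 0.8)
})

test_that("glasso matches an independent ADMM solver on small problems", {
  # ADMM with eigen-decomposition prox: an algorithmically independent
  # route to the same penalized likelihood optimum
  admm_glasso <- function(s, rho, iters = 4000, mu = 1) {
    p <- nrow(s)
    theta <- diag(p); z <- diag(p); u <- matrix(0, p, p)
    for (i in seq_len(iters)) {
      eg <- eigen((mu * (z - u) - s) / mu, symmetric = TRUE)
      ev <- (eg$values + sqrt(eg$values^2 + 4 / mu)) / 2
      theta <- eg$vectors %*% (ev * t(eg$vectors))
      z <- sign(theta + u) * pmax(abs(theta + u) - rho / mu, 0)
      u <- u + theta - z
    }
    z
  }
  for (seed in c(1, 2)) {
    set.seed(seed)
    p <- 5
    x <- matrix(rnorm(80 * p), 80, p)
    x[, 2] <- x[, 1] * 0.6 + rnorm(80, sd = 0.6)
    s <- cov(x)
    ours <- glasso_fit(s, rho = 0.15)$theta
    ref <- admm_glasso(s, rho = 0.15)
    expect_lt(max(abs(ours - ref)), 1e-4)
  }
})

test_that("glasso path flags the same strong edges as mb on planted data", {
  x <- chain_gaussian(250, 8, seed = 5, weight = 0.45)
  gl <- fit_network_path(x, method = "glasso")
  truth <- chain_edge_keys(8)
  f1s <- vapply(seq_along(gl$lambdas), function(l) {
    a <- gl$adj[[l]]
    ij <- which(a & upper.tri(a), arr.ind = TRUE)
    got <- paste(colnames(x)[ij[, 1]], colnames(x)[ij[, 2]], sep = "|")
    tp <- sum(got %in% truth)
    2 * tp / (length(got) + length(truth))
  }, numeric(1))
  expect_gte(max(f1s), 0.8)
  # positive association = positive partial correlation weight
  l_best <- which.max(f1s)
  w <- gl$weights[[l_best]]
  expect_true(all(w[cbind(1:7, 2:8)] > 0))
})

test_that("stars selects a stable graph: null data give a near-empty network", {
  set.seed(30)
  x <- matrix(rnorm(120 * 15), 120, 15)
  colnames(x) <- sprintf("V%02d", 1:15)
  rownames(x) <- sprintf("s%03d", 1:120)
  net <- stars_select(x, method = "mb", n_subsamples = 25, seed = 3)
  expect_lte(nrow(net$edges), 3)
  expect_true(all(net$sup_instability == cummax(net$instability)))
  # with a path whose head exceeds every subsample covariance, the empty
  # graph is always selected at the largest lambda: instability exactly 0
  lam <- lambda_path(x) * 4
  net_hi <- stars_select(x, method = "mb", lambdas = lam,
                         n_subsamples = 25, seed = 3)
  expect_equal(net_hi$instability[1], 0)
})

test_that("stars recovers the planted chain and is deterministic and order-invariant", {
  x <- chain_gaussian(300, 20, seed = 4)
  net <- stars_select(x, method = "mb", n_subsamples = 30, seed = 7)
  truth <- chain_edge_keys(20)
  got <- edge_keys(net$edges)
  expect_gte(sum(got %in% truth) / length(truth), 0.8)
  expect_lte(sum(!got %in% truth) / max(1, length(got)), 0.2)
  expect_true(all(net$edges$stability >= 0 & net$edges$stability <= 1))
  expect_true(all(net$edges$sign ==
                    ifelse(net$edges$weight >= 0, "positive", "negative")))

  net2 <- stars_select(x, method = "mb", n_subsamples = 30, seed = 7)
  expect_identical(net$edges, net2$edges)
  expect_identical(net$lambda_selected, net2$lambda_selected)

  perm <- sample(nrow(x))
  net3 <- stars_select(x[perm, ], method = "mb", n_subsamples = 30,
                       seed = 7)
  expect_identical(net$edges, net3$edges)
})

test_that("neighborhood extraction returns signed spokes with taxonomy", {
  edges <- tibble::tibble(
    otu_a = c("F_0257", "F_0257", "F_0257", "P_0001"),
    otu_b = c("F_0163", "P_0001", "P_0002", "P_0003"),
    sign = c("positive", "positive", "negative", "positive"),
    weight = c(0.4, 0.2, -0.1, 0.05),
    stability = c(1, 0.9, 0.8, 0.7))
  net <- structure(list(nodes = c("F_0257", "F_0163", "P_0001", "P_0002",
                                  "P_0003"),
                        edges = edges, method = "mb", empty = FALSE),
                   class = "coabundance_network")
  nb <- extract_neighborhood(net, "F_0257", sign = "positive")
  expect_setequal(nb$partner, c("F_0163", "P_0001"))
  nb_all <- extract_neighborhood(net, "F_0257", sign = "both")
  expect_setequal(nb_all$partner, c("F_0163", "P_0001", "P_0002"))

  tax <- tibble::tibble(otu_id = "F_0163", phylum = "Ascomycota",
                        class = "Orbiliomycetes", order = "Orbiliales",
                        family = "Orbiliaceae", genus = "Dactylellina",
                        annotation = "nematode-trapping fungus")
  nb_tax <- extract_neighborhood(net, "F_0257", sign = "positive",
                                 taxonomy = tax)
  expect_identical(nb_tax$genus[nb_tax$partner == "F_0163"],
                   "Dactylellina")

  expect_warning(out <- extract_neighborhood(net, "F_9999"),
                 "F_9999")
  expect_identical(nrow(out), 0L)
})
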