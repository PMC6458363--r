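#' Centered log-ratio transform of a count table
#'
#' Per sample: `z_i = log(c_i + pc) - mean_j log(c_j + pc)`. The CLR removes
#' the total-sum (compositional) constraint of sequencing counts, so
#' covariance among transformed OTUs reflects co-abundance rather than
#' closure artifacts; every row of the result sums to zero.
#'
#' @param table An `otu_tbl` (typically rarefied, prevalence-filtered and
#'   cross-kingdom merged) or a numeric sample-by-OTU matrix.
#' @param pseudocount Value added to every count before the log
#'   (default 1).
#' @return A numeric matrix (samples x OTUs, dimnames preserved).
#' @export
clr_transform <- function(table, pseudocount = 1) {
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  m <- if (is_otu_tbl(table)) as_count_matrix(table) else as.matrix(table)
  lg <- log(m + pseudocount)
  sweep(lg, 1, rowMeans(lg))
}

#' Regularization path for network inference
#'
#' Log-spaced descending sequence of `n_lambda` values from the maximum
#' absolute off-diagonal covariance of the CLR matrix down to
#' `min_ratio` times it — the standard path over which stability selection
#' scans.
#'
#' @param clr CLR matrix from [clr_transform()].
#' @param n_lambda Path length (default 20).
#' @param min_ratio Smallest lambda as a fraction of the largest
#'   (default 0.01).
#' @return Descending numeric vector.
#' @export
lambda_path <- function(clr, n_lambda = 20, min_ratio = 0.01) {
  s <- stats::cov(clr)
  lam_max <- max(abs(s[upper.tri(s)]))
  if (!is.finite(lam_max) || lam_max <= 0) {
    abort("degenerate covariance: no off-diagonal signal")
  }
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = n_lambda))
}

#' Fit a sparse co-abundance graph along a lambda path
#'
#' Two estimators of the conditional-dependence graph over CLR-transformed
#' OTUs:
#' * `mb` — Meinshausen-Buhlmann neighborhood selection: one lasso
#'   regression per node over the path; two OTUs are joined when either
#'   regression selects the other (OR rule). Edge weight is the directed
#'   coefficient of larger magnitude, whose sign gives the edge sign.
#' * `glasso` — graphical lasso on the CLR covariance (see [glasso_fit()]);
#'   edge weight is the partial correlation, i.e. the sign of the negated
#'   precision entry.
#'
#' @param clr CLR matrix (samples x OTUs).
#' @param method `"mb"` (default) or `"glasso"`.
#' @param lambdas Positive descending path; default [lambda_path()].
#' @return An object of class `rz_netpath`: list with `method`, `lambdas`,
#'   `adj` (list of logical adjacency matrices, one per lambda) and
#'   `weights` (matching numeric matrices).
#' @export
fit_network_path <- function(clr, method = c("mb", "glasso"),
                             lambdas = NULL) {
  method <- match.arg(method)
  p <- ncol(clr)
  if (p < 2) abort("need at least two OTUs")
  vars <- apply(clr, 2, var)
  if (any(vars < 1e-12)) {
    abort(paste0("degenerate (constant) CLR columns: ",
                 paste(head(colnames(clr)[vars < 1e-12], 5),
                       collapse = ", ")))
  }
  if (is.null(lambdas)) lambdas <- lambda_path(clr)
  if (any(diff(lambdas) >= 0) || any(lambdas <= 0)) {
    abort("lambdas must be positive and strictly descending")
  }
  if (method == "mb") mb_path(clr, lambdas) else glasso_path(clr, lambdas)
}

mb_path <- function(clr, lambdas) {
  n <- nrow(clr); p <- ncol(clr)
  nl <- length(lambdas)
  # betas[[l]] is p x p: column j = coefficients of regressing node j on rest
  betas <- lapply(seq_len(nl), function(l) matrix(0, p, p))
  for (j in seq_len(p)) {
    x <- clr[, -j, drop = FALSE]
    y <- clr[, j]
    if (p == 2) {
      cxy <- sum((x - mean(x)) * (y - mean(y))) / n
      vxx <- sum((x - mean(x))^2) / n
      for (l in seq_len(nl)) {
        b <- soft_threshold(cxy, lambdas[l]) / vxx
        betas[[l]][-j, j] <- b
      }
    } else {
      fit <- glmnet::glmnet(x, y, lambda = lambdas, standardize = FALSE,
                            intercept = TRUE)
      cf <- as.matrix(fit$beta)
      # glmnet may drop path tail; pad with the last fitted column
      if (ncol(cf) < nl) {
        cf <- cbind(cf, cf[, rep(ncol(cf), nl - ncol(cf)), drop = FALSE])
      }
      for (l in seq_len(nl)) betas[[l]][-j, j] <- cf[, l]
    }
  }
  adj <- list(); weights <- list()
  for (l in seq_len(nl)) {
    b <- betas[[l]]
    a <- (b != 0) | (t(b) != 0)            # OR rule
    diag(a) <- FALSE
    w <- ifelse(abs(b) >= abs(t(b)), b, t(b))
    w[!a] <- 0
    dimnames(a) <- dimnames(w) <- list(colnames(clr), colnames(clr))
    adj[[l]] <- a; weights[[l]] <- w
  }
  structure(list(method = "mb", lambdas = lambdas, adj = adj,
                 weights = weights), class = "rz_netpath")
}

glasso_path <- function(clr, lambdas) {
  s <- stats::cov(clr)
  adj <- list(); weights <- list()
  theta <- NULL
  for (l in seq_along(lambdas)) {
    fit <- glasso_fit(s, rho = lambdas[l], theta_init = theta)
    theta <- fit$theta                      # warm start down the path
    pc <- -theta / sqrt(outer(diag(theta), diag(theta)))
    diag(pc) <- 0
    a <- abs(theta) > 1e-8
    diag(a) <- FALSE
    w <- pc * a
    dimnames(a) <- dimnames(w) <- list(colnames(clr), colnames(clr))
    adj[[l]] <- a; weights[[l]] <- w
  }
  structure(list(method = "glasso", lambdas = lambdas, adj = adj,
                 weights = weights), class = "rz_netpath")
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' StARS stability selection of a co-abundance network
#'
#' Stability Approach to Regularization Selection: the graph path is
#' refitted on `n_subsamples` random subsamples (without replacement, size
#' `floor(subsample_ratio * n)`); for each lambda the graph instability is
#' the mean over all node pairs of `2 * theta * (1 - theta)`, where `theta`
#' is the pair's selection frequency across subsamples. Instability is
#' monotonized from the sparse end (running maximum along descending
#' lambda) and the selected lambda is the smallest one whose monotonized
#' instability stays at or below `beta`. The final network is refit on the
#' full data at that lambda; each retained edge carries its subsample
#' selection frequency as a stability score.
#'
#' @inheritParams fit_network_path
#' @param n_subsamples Number of subsamples (default 50).
#' @param subsample_ratio Fraction of samples per subsample; default
#'   `min(0.8, 10 * sqrt(n) / n)`.
#' @param beta Instability budget (default 0.05).
#' @param seed Integer seed.
#' @return A `coabundance_network`: list with `nodes`, `edges` (tibble:
#'   `otu_a`, `otu_b`, `sign`, `weight`, `stability`), `lambda_selected`,
#'   `lambdas`, `instability`, `sup_instability`, `method`, `beta`,
#'   `n_subsamples`, `subsample_ratio`, `seed` and `empty` (flag set when
#'   no lambda meets the budget and the empty graph is returned).
#' @export
stars_select <- function(clr, method = c("mb", "glasso"), lambdas = NULL,
                         n_subsamples = 50, subsample_ratio = NULL,
                         beta = 0.05, seed = 1) {
  method <- match.arg(method)
  if (n_subsamples < 2) abort("n_subsamples must be >= 2")
  if (!is.null(rownames(clr))) {
    clr <- clr[order(rownames(clr)), , drop = FALSE]  # order-invariant
  }
  n <- nrow(clr); p <- ncol(clr)
  if (is.null(lambdas)) lambdas <- lambda_path(clr)
  if (is.null(subsample_ratio)) subsample_ratio <- min(0.8, 10 * sqrt(n) / n)
  b_size <- max(2, floor(subsample_ratio * n))
  nl <- length(lambdas)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  freq <- lapply(seq_len(nl), function(l) matrix(0, p, p))
  for (b in seq_len(n_subsamples)) {
    idx <- sample.int(n, b_size)
    path <- fit_network_path(clr[idx, , drop = FALSE], method = method,
                             lambdas = lambdas)
    for (l in seq_len(nl)) freq[[l]] <- freq[[l]] + path$adj[[l]]
  }
  theta <- lapply(freq, function(f) f / n_subsamples)
  n_pairs <- p * (p - 1) / 2
  instab <- vapply(theta, function(th) {
    xi <- 2 * th * (1 - th)
    sum(xi[upper.tri(xi)]) / n_pairs
  }, numeric(1))
  sup_instab <- cummax(instab)               # lambdas are descending

  ok <- which(sup_instab <= beta)
  empty <- length(ok) == 0
  sel <- if (empty) NA_integer_ else max(ok)  # smallest lambda within budget

  nodes <- colnames(clr)
  if (empty) {
    edges <- tibble(otu_a = character(), otu_b = character(),
                    sign = character(), weight = numeric(),
                    stability = numeric())
    lambda_selected <- NA_real_
  } else {
    full <- fit_network_path(clr, method = method, lambdas = lambdas)
    a <- full$adj[[sel]]; w <- full$weights[[sel]]; th <- theta[[sel]]
    ij <- which(a & upper.tri(a), arr.ind = TRUE)
    edges <- tibble(otu_a = nodes[ij[, 1]], otu_b = nodes[ij[, 2]],
                    sign = ifelse(w[ij] >= 0, "positive", "negative"),
                    weight = w[ij], stability = th[ij])
    lambda_selected <- lambdas[sel]
  }
  structure(list(nodes = nodes, edges = edges,
                 lambda_selected = lambda_selected, lambdas = lambdas,
                 instability = instab, sup_instability = sup_instab,
                 method = method, beta = beta,
                 n_subsamples = n_subsamples,
                 subsample_ratio = subsample_ratio, seed = seed,
                 empty = empty),
            class = "coabundance_network")
}

#' Infer a co-abundance network from a merged count table
#'
#' Convenience wrapper: CLR transform then [stars_select()]. The input
#' should already be rarefied, prevalence-filtered and (for cross-kingdom
#' networks) merged via [merge_tables()].
#'
#' @param table An `otu_tbl`.
#' @param pseudocount Passed to [clr_transform()].
#' @inheritParams stars_select
#' @return A `coabundance_network`.
#' @export
infer_network <- function(table, pseudocount = 1,
                          method = c("mb", "glasso"), lambdas = NULL,
                          n_subsamples = 50, subsample_ratio = NULL,
                          beta = 0.05, seed = 1) {
  stars_select(clr_transform(table, pseudocount), method = method,
               lambdas = lambdas, n_subsamples = n_subsamples,
               subsample_ratio = subsample_ratio, beta = beta, seed = seed)
}

#' @export
print.coabundance_network <- function(x, ...) {
  cat(sprintf("co-abundance network (%s, StARS beta = %g): %d nodes, %d edges\n",
              x$method, x$beta, length(x$nodes), nrow(x$edges)))
  if (x$empty) cat("no lambda met the instability budget; empty network\n")
  else cat(sprintf("lambda selected = %.4g (%d positive, %d negative edges)\n",
                   x$lambda_selected, sum(x$edges$sign == "positive"),
                   sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Tidy a co-abundance network
#'
#' @param x A `coabundance_network`.
#' @param ... Unused.
#' @return `tidy()`: the signed edge list; `glance()`: selection summary.
#' @exportS3Method generics::tidy
tidy.coabundance_network <- function(x, ...) x$edges

#' @rdname tidy.coabundance_network
#' @exportS3Method generics::glance
glance.coabundance_network <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         lambda_selected = x$lambda_selected, method = x$method,
         beta = x$beta, empty = x$empty)
}

#' Signed neighborhood of focal OTUs
#'
#' All network edges incident to the given focal OTUs with the requested
#' sign, optionally annotated with the partner OTU's taxonomy — the
#' "who co-occurs with the nematophagous fungi" view of a network.
#'
#' @param net A `coabundance_network`.
#' @param focal Character vector of focal OTU ids; ids absent from the
#'   network trigger a warning each and contribute no rows.
#' @param sign `"positive"`, `"negative"` or `"both"`.
#' @param taxonomy Optional taxonomy tibble (see [read_taxonomy()]) joined
#'   onto the partner OTU.
#' @return A tibble with columns `focal`, `partner`, `sign`, `weight`,
#'   `stability` (+ taxonomy columns when supplied).
#' @export
extract_neighborhood <- function(net, focal,
                                 sign = c("positive", "negative", "both"),
                                 taxonomy = NULL) {
  sign <- match.arg(sign)
  missing_ids <- setdiff(focal, net$nodes)
  for (id in missing_ids) {
    warn(paste0("focal OTU not in network: ", id))
  }
  e <- net$edges
  if (sign != "both") e <- filter(e, .data$sign == !!sign)
  hit_a <- e$otu_a %in% focal
  hit_b <- e$otu_b %in% focal
  out <- bind_rows(
    tibble(focal = e$otu_a[hit_a], partner = e$otu_b[hit_a],
           sign = e$sign[hit_a], weight = e$weight[hit_a],
           stability = e$stability[hit_a]),
    tibble(focal = e$otu_b[hit_b], partner = e$otu_a[hit_b],
           sign = e$sign[hit_b], weight = e$weight[hit_b],
           stability = e$stability[hit_b]))
  out <- arrange(out, .data$focal, desc(abs(.data$weight)))
  if (!is.null(taxonomy)) {
    out <- left_join(out, taxonomy, by = c(partner = "otu_id"))
  }
  out
}

#' Export a network to GraphML
#'
#' @param net A `coabundance_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
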