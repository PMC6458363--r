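#' Permutational multivariate analysis of variance (sequential SS)
#'
#' Partitions a dissimilarity matrix by an ordered list of explanatory
#' terms using the Gower-centered inner-product formulation: with
#' `A = -d^2 / 2` and `G = J A J` (J the centering projector), the sum of
#' squares attributable to a nested model with hat matrix `H` is `tr(H G)`.
#' Sums of squares are *sequential* (type I) in the order `terms` is given
#' — on non-orthogonal designs, reordering the terms changes the per-term
#' partition. The pseudo-F for each term is
#' `(SS_term / df_term) / (SS_resid / df_resid)`; significance comes from
#' unrestricted permutation of sample rows, recomputing the full sequential
#' table for every permutation.
#'
#' Factors contribute `levels - 1` df, numeric covariates 1 df. Samples
#' with a missing value in any term (e.g. unrecorded dry mass) are dropped
#' with a message. In the standard field design `sampling_set` is entered
#' before `plant_state` or `dry_mass` so the line effect is absorbed first.
#'
#' @param d A [stats::dist] or symmetric matrix of dissimilarities, labelled
#'   with sample ids.
#' @param meta Metadata tibble with a `sample_id` column and the term
#'   variables.
#' @param terms Character vector of column names, in the order they enter
#'   the model.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param exact If `TRUE` (only for n <= 8), enumerate all `n!` row
#'   orderings instead of sampling; p-values are then exact proportions
#'   including the identity.
#' @return An `rz_permanova` object; see [tidy.rz_permanova()].
#' @export
permanova <- function(d, meta, terms, n_perm = 10000, seed = 1,
                      exact = FALSE) {
  d <- as_dist_checked(d)
  ids <- attr(d, "Labels")
  if (is.null(ids)) abort("distance matrix must carry sample labels")
  if (!length(terms)) abort("terms must be non-empty")
  miss <- setdiff(terms, names(meta))
  if (length(miss)) {
    abort(paste0("term(s) not in metadata: ", paste(miss, collapse = ", ")))
  }
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) abort("metadata missing for some samples")

  ok <- complete.cases(meta[terms])
  if (any(!ok)) {
    inform(sprintf("permanova: dropping %d sample(s) with missing term values",
                   sum(!ok)))
    keep <- which(ok)
    dm <- as.matrix(d)[keep, keep, drop = FALSE]
    d <- stats::as.dist(dm)
    meta <- meta[keep, , drop = FALSE]
  }
  n <- attr(d, "Size")

  # Gower-centered inner-product matrix
  a <- -0.5 * as.matrix(d)^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a))
  g <- g + mean(a)

  # per-term model-matrix blocks
  blocks <- lapply(terms, function(tm) {
    v <- meta[[tm]]
    if (is.character(v) || is.logical(v)) v <- factor(v)
    if (is.factor(v)) {
      v <- droplevels(v)
      if (nlevels(v) < 2) {
        abort(paste0("term '", tm, "' is constant (single level)"))
      }
      stats::model.matrix(~v)[, -1, drop = FALSE]
    } else {
      matrix(as.numeric(v), ncol = 1)
    }
  })
  df <- vapply(blocks, ncol, integer(1))
  if (n < sum(df) + 2) abort("too few samples for the requested terms")

  # nested hat matrices H_0 (intercept) .. H_K (full model)
  x <- matrix(1, n, 1)
  hats <- vector("list", length(blocks) + 1)
  hats[[1]] <- hat_matrix(x)
  for (k in seq_along(blocks)) {
    x <- cbind(x, blocks[[k]])
    hats[[k + 1]] <- hat_matrix(x)
  }
  df <- vapply(seq_along(blocks), function(k) {
    as.integer(round(sum(diag(hats[[k + 1]])) - sum(diag(hats[[k]]))))
  }, integer(1))
  df_resid <- n - 1L - sum(df)
  if (df_resid < 1) abort("no residual degrees of freedom")

  seq_ss <- function(gp) {
    tr <- vapply(hats, function(h) sum(h * gp), numeric(1))
    diff(tr)
  }
  ss_total <- sum(diag(g))
  ss <- seq_ss(g)
  ss_resid <- ss_total - sum(ss) - sum(hats[[1]] * g)
  f_obs <- (ss / df) / (ss_resid / df_resid)

  perm_f <- function(p) {
    gp <- g[p, p]
    ssp <- seq_ss(gp)
    ssr <- sum(diag(gp)) - sum(ssp) - sum(hats[[1]] * gp)
    (ssp / df) / (ssr / df_resid)
  }

  if (exact) {
    if (n > 8) abort("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    fs <- vapply(perms, perm_f, numeric(length(terms)))
    fs <- matrix(fs, nrow = length(terms))
    p_val <- rowMeans(fs >= f_obs - 1e-12)
    n_used <- ncol(fs)
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
    count <- numeric(length(terms))
    for (t in seq_len(n_perm)) {
      fp <- perm_f(sample.int(n))
      count <- count + (fp >= f_obs - 1e-12)
    }
    p_val <- (1 + count) / (n_perm + 1)
    n_used <- n_perm
  }

  structure(list(
    table = tibble(term = terms, df = df, ss = ss,
                   r2 = ss / ss_total, f = f_obs, p = p_val),
    residual = tibble(df = df_resid, ss = ss_resid,
                      r2 = ss_resid / ss_total),
    ss_total = ss_total, n = n, n_perm = n_used, seed = seed,
    exact = exact), class = "rz_permanova")
}

hat_matrix <- function(x) {
  q <- qr.Q(qr(x))[, seq_len(qr(x)$rank), drop = FALSE]
  tcrossprod(q)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' @export
print.rz_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %s permutations)\n",
              if (x$exact) "exact enumeration of" else format(x$n_perm)))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  cat(sprintf("residual: df = %d, SS = %.4f; total SS = %.4f (n = %d)\n",
              x$residual$df, x$residual$ss, x$ss_total, x$n))
  invisible(x)
}

#' Tidy a PERMANOVA fit
#'
#' @param x An `rz_permanova` object.
#' @param ... Unused.
#' @return `tidy()`: one row per term plus a `residual` row, with columns
#'   `term`, `df`, `ss`, `r2`, `f`, `p`. `glance()`: one row with total SS,
#'   n, and permutation count.
#' @exportS3Method generics::tidy
tidy.rz_permanova <- function(x, ...) {
  bind_rows(x$table,
            tibble(term = "residual", df = x$residual$df,
                   ss = x$residual$ss, r2 = x$residual$r2,
                   f = NA_real_, p = NA_real_))
}

#' @rdname tidy.rz_permanova
#' @exportS3Method generics::glance
glance.rz_permanova <- function(x, ...) {
  tibble(ss_total = x$ss_total, n = x$n, n_perm = x$n_perm,
         exact = x$exact)
}
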