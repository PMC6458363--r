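#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds samples in `k` dimensions so that the rank order of configuration
#' distances matches the rank order of the input dissimilarities as closely
#' as possible. Each start alternates (i) monotone (isotonic) regression of
#' configuration distances on the dissimilarities — Kruskal's primary
#' approach to ties, which lets tied dissimilarities receive different
#' fitted values — with (ii) a Guttman majorization update of the
#' configuration. Iteration stops when stress-1,
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`, improves by less than `tol`; an
#' update that fails to improve stress is rejected, so the recorded stress
#' path is non-increasing. One start uses classical (metric) scaling; the
#' remainder are random Gaussian configurations. The best start wins and
#' the returned configuration is centered. Solutions are identified only up
#' to rotation and reflection; compare configurations via Procrustes, not
#' coordinates.
#'
#' @param d A [stats::dist] or symmetric matrix of dissimilarities.
#' @param k Embedding dimension (default 2).
#' @param n_starts Number of starts including the metric one (default 20).
#' @param seed Integer seed for the random starts.
#' @param max_iter Iteration cap per start (default 500).
#' @param tol Stress improvement threshold for convergence (default 1e-7).
#' @return An `rz_nmds` object with elements `points` (tibble: `sample_id`
#'   plus `NMDS1..k`), `stress`, `converged`, `best_start`, `n_starts` and
#'   `stress_path` (stress per iteration of the winning start).
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1, max_iter = 500,
                 tol = 1e-7) {
  d <- as_dist_checked(d)
  if (k < 1) abort("k must be >= 1")
  n <- attr(d, "Size")
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  delta <- as.vector(d)
  if (all(delta == 0)) abort("all dissimilarities are zero")

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  metric0 <- suppressWarnings(cmdscale(d, k = k))
  if (ncol(metric0) < k) {
    metric0 <- cbind(metric0,
                     matrix(rnorm(n * (k - ncol(metric0)), sd = 1e-4), n))
  }
  starts <- c(list(metric0),
              lapply(seq_len(max(0, n_starts - 1)),
                     function(i) matrix(rnorm(n * k), n, k)))

  best <- NULL
  for (i in seq_along(starts)) {
    fit <- nmds_one_start(starts[[i]], delta, n, k, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best$start <- i
    }
  }
  pts <- scale(best$conf, center = TRUE, scale = FALSE)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(
    points = bind_cols(tibble(sample_id = ids),
                       as_tibble(as.data.frame(pts))),
    stress = best$stress, converged = best$converged,
    best_start = best$start, n_starts = length(starts),
    stress_path = best$path), class = "rz_nmds")
}

nmds_one_start <- function(conf, delta, n, k, max_iter, tol) {
  stress_of <- function(dv, dhat) sqrt(sum((dv - dhat)^2) / sum(dv^2))
  dv <- as.vector(dist(conf))
  dhat <- monotone_fit(delta, dv)
  s <- stress_of(dv, dhat)
  path <- s
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    new_conf <- guttman_update(conf, dhat, dv, n)
    new_dv <- as.vector(dist(new_conf))
    new_dhat <- monotone_fit(delta, new_dv)
    new_s <- stress_of(new_dv, new_dhat)
    if (new_s > s) break                      # reject non-improving step
    improved <- s - new_s
    conf <- new_conf; dv <- new_dv; dhat <- new_dhat; s <- new_s
    path <- c(path, s)
    if (improved < tol) { converged <- TRUE; break }
  }
  list(conf = conf, stress = s, converged = converged, path = path)
}

# isotonic regression of configuration distances on dissimilarity order;
# ties in delta are pre-sorted by increasing distance (primary approach)
monotone_fit <- function(delta, dv) {
  ord <- order(delta, dv)
  fit <- isoreg(dv[ord])$yf
  out <- numeric(length(dv))
  out[ord] <- fit
  out
}

guttman_update <- function(conf, dhat, dv, n) {
  ratio <- ifelse(dv > 1e-12, dhat / dv, 0)
  b <- matrix(0, n, n)
  b[lower.tri(b)] <- -ratio
  b <- b + t(b)
  diag(b) <- -rowSums(b)
  (b %*% conf) / n
}

#' @export
print.rz_nmds <- function(x, ...) {
  cat(sprintf("NMDS: %d points, k = %d, stress = %.4f (%s, best of %d starts)\n",
              nrow(x$points), ncol(x$points) - 1, x$stress,
              if (x$converged) "converged" else "not converged",
              x$n_starts))
  invisible(x)
}

#' Tidy an NMDS fit
#'
#' @param x An `rz_nmds` object.
#' @param ... Unused.
#' @return `tidy()`: the sample coordinates; `glance()`: stress and
#'   convergence summary.
#' @exportS3Method generics::tidy
tidy.rz_nmds <- function(x, ...) x$points

#' @rdname tidy.rz_nmds
#' @exportS3Method generics::glance
glance.rz_nmds <- function(x, ...) {
  tibble(stress = x$stress, converged = x$converged,
         best_start = x$best_start, n_starts = x$n_starts)
}

#' Procrustes root-mean-square error between two configurations
#'
#' Aligns `y` to `x` by translation, scaling and orthogonal rotation (with
#' reflection allowed) and returns the RMS coordinate difference — the
#' rotation-invariant way to compare NMDS solutions.
#'
#' @param x,y Numeric matrices (or `rz_nmds` objects) with matching rows.
#' @return RMS error after optimal superimposition.
#' @export
procrustes_error <- function(x, y) {
  if (inherits(x, "rz_nmds")) x <- as.matrix(x$points[-1])
  if (inherits(y, "rz_nmds")) y <- as.matrix(y$points[-1])
  x <- scale(x, scale = FALSE); y <- scale(y, scale = FALSE)
  s <- svd(crossprod(x, y))
  rot <- s$v %*% t(s$u)
  scl <- sum(s$d) / sum(y^2)
  err <- x - scl * y %*% rot
  sqrt(mean(rowSums(err^2)))
}
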