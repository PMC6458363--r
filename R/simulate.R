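#' Simulate a rhizosphere community with planted ground truth
#'
#' Generates a sample-by-OTU count table, matching metadata and a
#' ground-truth record, emulating the features of field amplicon data the
#' downstream statistics must cope with:
#'
#' * heavy-tailed baseline relative abundances (ranked log-normal,
#'   `baseline_sdlog`);
#' * host plant states with unbalanced sample sizes (default 97 green /
#'   19 yellow / 15 no_leaf), assigned uniformly at random to positions;
#' * planted state-preferential OTUs: each `(otu, state, fold)` row of the
#'   truth multiplies that OTU's abundance by `fold` in samples of that
#'   state (compositions are renormalized afterwards, so large planted
#'   effects dilute everything else in that state);
#' * latent co-abundance structure: OTUs named in `graph_edges` share a
#'   Gaussian copula whose precision matrix has the planted support;
#' * a latent AR(1) spatial field along positions within each sampling set
#'   (`spatial_rho`, loading scale `spatial_scale`), sets alternating along
#'   the planting order;
#' * Dirichlet-multinomial counts (total concentration `concentration`)
#'   at per-sample depths that are fixed (`depth`) or log-normal
#'   (`depth_meanlog`, `depth_sdlog`).
#'
#' With no planted effects (`preferential` empty), `spatial_rho = 0` and no
#' graph, the state labels are exchangeable by construction — the null
#' configuration used for calibration runs.
#'
#' @param n_per_state Named or ordered triple of sample counts for green,
#'   yellow, no_leaf.
#' @param n_otus Number of OTUs.
#' @param preferential `NULL`, or a tibble with columns `otu` (integer rank
#'   index or OTU id), `state`, `fold` (>= 1). See [plant_preferential()]
#'   for the default layout used when only counts are given.
#' @param graph_edges `NULL`, or a tibble with columns `otu_a`, `otu_b`
#'   (rank indices or ids) and optional `weight` (partial-correlation-scale
#'   precision entries, default 0.35; sign = association sign).
#' @param baseline_sdlog Log-sd of the ranked log-normal baseline
#'   (default 1.5).
#' @param latent_sd Scale of the latent graph-copula component on log
#'   abundance (default 0.6); only OTUs named in `graph_edges` receive it.
#' @param spatial_rho AR(1) coefficient of the spatial field, `|rho| < 1`
#'   (default 0.4).
#' @param spatial_scale Loading scale of the spatial field on log
#'   abundance (default 0.3).
#' @param concentration Dirichlet-multinomial total concentration
#'   (default 500; larger = closer to multinomial).
#' @param depth Fixed per-sample read depth; `NULL` for log-normal depths.
#' @param depth_meanlog,depth_sdlog Log-normal depth model used when
#'   `depth` is `NULL` (defaults `log(2000)` and 0.35).
#' @param marker,compartment Labels stamped on the output table.
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @return A list with elements `table` (`otu_tbl`), `metadata` (tibble)
#'   and `truth` (list: `preferential`, `graph_edges`, `spatial_rho`,
#'   `spatial_scale`, `latent_sd`, `baseline` named vector, `concentration`,
#'   `depth` model, `seed`).
#' @export
generate_community <- function(n_per_state = c(green = 97, yellow = 19,
                                               no_leaf = 15),
                               n_otus = 150,
                               preferential = NULL,
                               graph_edges = NULL,
                               baseline_sdlog = 1.5,
                               latent_sd = 0.6,
                               spatial_rho = 0.4,
                               spatial_scale = 0.3,
                               concentration = 500,
                               depth = NULL,
                               depth_meanlog = log(2000),
                               depth_sdlog = 0.35,
                               marker = c("16S", "ITS"),
                               compartment = c("root", "soil"),
                               seed = 1) {
  marker <- match.arg(marker)
  compartment <- match.arg(compartment)
  if (length(n_per_state) != 3) abort("n_per_state must have three entries")
  if (abs(spatial_rho) >= 1) abort("|spatial_rho| must be < 1")
  if (n_otus < 2) abort("need at least two OTUs")
  states <- c("green", "yellow", "no_leaf")
  n_samples <- sum(n_per_state)
  otu_id <- sprintf("S_%04d", seq_len(n_otus))

  pref <- normalize_preferential(preferential, otu_id)
  edges <- normalize_graph(graph_edges, otu_id)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  # ranked heavy-tailed baseline composition
  baseline <- sort(rlnorm(n_otus, meanlog = 0, sdlog = baseline_sdlog),
                   decreasing = TRUE)
  baseline <- baseline / sum(baseline)
  names(baseline) <- otu_id

  # sampling design: sets alternate along the planting order, positions
  # increment within set; states assigned uniformly at random
  set_vec <- rep(c(1L, 2L), length.out = n_samples)
  position <- stats::ave(seq_len(n_samples), set_vec, FUN = seq_along)
  state_vec <- sample(rep(states, times = n_per_state))
  sample_id <- sprintf("S%03d", seq_len(n_samples))

  # latent Gaussian structure: AR(1) spatial drift plus, for graph OTUs,
  # a copula draw from the planted precision; all remaining sample-level
  # noise enters through the Dirichlet-multinomial stage
  z <- matrix(0, n_samples, n_otus)
  if (nrow(edges)) {
    gset <- sort(unique(c(edges$otu_a, edges$otu_b)))
    ch <- graph_copula_chol(edges, gset)
    z[, match(gset, otu_id)] <-
      matrix(rnorm(n_samples * length(gset)), n_samples) %*% ch
  }
  loading <- rnorm(n_otus)
  u <- numeric(n_samples)
  for (s in c(1L, 2L)) {
    idx <- which(set_vec == s)
    idx <- idx[order(position[idx])]
    u[idx] <- ar1_series(length(idx), spatial_rho)
  }
  logab <- matrix(log(baseline), n_samples, n_otus, byrow = TRUE) +
    latent_sd * z + spatial_scale * outer(u, loading)

  # planted fold enrichment in the target state
  if (nrow(pref)) {
    for (r in seq_len(nrow(pref))) {
      rows <- state_vec == pref$state[r]
      col <- match(pref$otu_id[r], otu_id)
      logab[rows, col] <- logab[rows, col] + log(pref$fold[r])
    }
  }

  depths <- if (!is.null(depth)) rep(as.integer(depth), n_samples)
            else pmax(100L, as.integer(round(
              rlnorm(n_samples, depth_meanlog, depth_sdlog))))

  counts <- matrix(0L, n_samples, n_otus,
                   dimnames = list(sample_id, otu_id))
  for (s in seq_len(n_samples)) {
    p <- exp(logab[s, ] - max(logab[s, ]))
    p <- p / sum(p)
    g <- rgamma(n_otus, shape = concentration * p, rate = 1)
    if (sum(g) <= 0) g <- p
    counts[s, ] <- as.integer(rmultinom(1, depths[s], g / sum(g)))
  }

  dm_mean <- c(green = 12, yellow = 6, no_leaf = 2.5)
  meta <- tibble(sample_id = sample_id,
                 plant_state = factor(state_vec, levels = states),
                 sampling_set = set_vec,
                 position = as.integer(position),
                 dry_mass = round(pmax(0.2,
                   rnorm(n_samples, dm_mean[state_vec], 2)), 2))

  list(table = otu_table(counts, marker = marker,
                         compartment = compartment),
       metadata = meta,
       truth = list(preferential = pref, graph_edges = edges,
                    spatial_rho = spatial_rho,
                    spatial_scale = spatial_scale,
                    latent_sd = latent_sd,
                    baseline = baseline,
                    concentration = concentration,
                    depth = list(fixed = depth,
                                 meanlog = depth_meanlog,
                                 sdlog = depth_sdlog),
                    seed = seed))
}

#' Default layout of planted state-preferential OTUs
#'
#' Plants OTUs in triples of *consecutive* abundance ranks, each triple
#' split across the three plant states (with the within-triple assignment
#' rotating from triple to triple). Consecutive ranks carry near-identical
#' baseline mass, so every state receives almost exactly the same total
#' planted mass. Balancing matters: compositions are renormalized per
#' sample, so unequal planted mass across states would dilute null OTUs
#' differently by state and break label exchangeability for the unplanted
#' majority. Triples are spread from the 10th-percentile rank (keeping the
#' community's dominant OTUs unplanted, as pathogen-responsive taxa are
#' rarely the dominants) down to the 90th, so planted effects span roughly
#' two orders of magnitude of baseline abundance.
#'
#' @param n Number of planted OTUs.
#' @param n_otus Community size the ranks index into.
#' @param fold Fold enrichment (>= 1) applied in the target state.
#' @return A tibble with columns `otu` (rank index), `state`, `fold`.
#' @export
plant_preferential <- function(n, n_otus, fold = 8) {
  if (fold < 1) abort("fold must be >= 1")
  n_triples <- ceiling(n / 3)
  start <- max(3, round(0.1 * n_otus))
  base <- round(seq(start, 0.9 * n_otus - 2, length.out = n_triples))
  states <- c("green", "yellow", "no_leaf")
  out <- tibble(otu = integer(), state = character())
  for (t in seq_len(n_triples)) {
    rot <- states[((t - 1 + 0:2) %% 3) + 1]
    out <- bind_rows(out, tibble(otu = base[t] + 0:2, state = rot))
  }
  out <- out[seq_len(min(n, nrow(out))), ]
  out <- out[!duplicated(out$otu) & out$otu <= n_otus, ]
  mutate(out, fold = fold)
}

#' Chain-graph precision support over a set of OTU ranks
#'
#' Consecutive OTUs in `ranks` are linked, the classic planted structure
#' for testing sparse precision recovery.
#'
#' @param ranks Integer OTU rank indices.
#' @param weight Off-diagonal precision entry (default 0.35; negative
#'   precision entry = positive association).
#' @return A tibble with columns `otu_a`, `otu_b`, `weight`.
#' @export
chain_graph <- function(ranks, weight = 0.35) {
  if (length(ranks) < 2) abort("need at least two OTUs for a chain")
  tibble(otu_a = ranks[-length(ranks)], otu_b = ranks[-1],
         weight = weight)
}

normalize_preferential <- function(pref, otu_id) {
  if (is.null(pref) || !nrow(as_tibble(pref))) {
    return(tibble(otu_id = character(), state = character(),
                  fold = numeric()))
  }
  pref <- as_tibble(pref)
  if (!all(c("otu", "state", "fold") %in% names(pref)) &&
      !all(c("otu_id", "state", "fold") %in% names(pref))) {
    abort("preferential needs columns otu (or otu_id), state, fold")
  }
  id <- if ("otu_id" %in% names(pref)) pref$otu_id
        else resolve_otu(pref$otu, otu_id, "preferential")
  if (any(pref$fold < 1)) abort("planted folds must be >= 1")
  bad <- setdiff(unique(pref$state), c("green", "yellow", "no_leaf"))
  if (length(bad)) abort(paste0("unknown planted state: ", bad[1]))
  if (!all(id %in% otu_id)) {
    abort("planted OTU not present in the community (infeasible truth)")
  }
  tibble(otu_id = id, state = pref$state, fold = as.numeric(pref$fold))
}

normalize_graph <- function(edges, otu_id) {
  if (is.null(edges) || !nrow(as_tibble(edges))) {
    return(tibble(otu_a = character(), otu_b = character(),
                  weight = numeric()))
  }
  edges <- as_tibble(edges)
  if (!"weight" %in% names(edges)) edges$weight <- 0.35
  a <- resolve_otu(edges$otu_a, otu_id, "graph_edges")
  b <- resolve_otu(edges$otu_b, otu_id, "graph_edges")
  if (any(a == b)) abort("graph_edges may not contain self-edges")
  tibble(otu_a = a, otu_b = b, weight = as.numeric(edges$weight))
}

resolve_otu <- function(x, otu_id, what) {
  if (is.numeric(x)) {
    if (any(x < 1 | x > length(otu_id))) {
      abort(paste0(what, ": OTU rank index out of range (infeasible truth)"))
    }
    otu_id[as.integer(x)]
  } else {
    if (!all(x %in% otu_id)) {
      abort(paste0(what, ": unknown OTU id (infeasible truth)"))
    }
    as.character(x)
  }
}

# Cholesky factor of the correlation implied by the planted precision
# support; off-diagonals are shrunk if needed to keep the matrix PD
graph_copula_chol <- function(edges, gset) {
  q <- length(gset)
  omega <- diag(q)
  ia <- match(edges$otu_a, gset); ib <- match(edges$otu_b, gset)
  for (r in seq_along(ia)) {
    omega[ia[r], ib[r]] <- omega[ia[r], ib[r]] - edges$weight[r]
    omega[ib[r], ia[r]] <- omega[ia[r], ib[r]]
  }
  off <- omega - diag(q)
  shrink <- 1
  while (min(eigen(diag(q) + shrink * off, symmetric = TRUE,
                   only.values = TRUE)$values) < 1e-3 && shrink > 1e-3) {
    shrink <- shrink * 0.8
  }
  omega <- diag(q) + shrink * off
  sigma <- solve(omega)
  d <- sqrt(diag(sigma))
  chol(sigma / outer(d, d))
}

#' Write a simulated bundle to disk in the package's file dialects
#'
#' Writes `otu_table.tsv`, `metadata.tsv`, `truth.json` and a
#' `manifest.json` recording seeds and parameters, such that
#' [read_otu_table()] / [read_sample_metadata()] round-trip the tables
#' exactly.
#'
#' @param bundle Output of [generate_community()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_otu_table(bundle$table, file.path(dir, "otu_table.tsv"))
  write_sample_metadata(bundle$metadata, file.path(dir, "metadata.tsv"))
  truth <- bundle$truth
  truth$baseline <- as.list(truth$baseline)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    seed = bundle$truth$seed,
    n_samples = nrow(bundle$table),
    n_otus = length(otu_ids(bundle$table)),
    marker = otu_marker(bundle$table),
    compartment = otu_compartment(bundle$table),
    files = c("otu_table.tsv", "metadata.tsv", "truth.json"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

ar1_series <- function(n, rho) {
  if (n == 0) return(numeric())
  e <- rnorm(n)
  u <- numeric(n)
  u[1] <- e[1]
  if (n > 1) {
    for (t in 2:n) u[t] <- rho * u[t - 1] + sqrt(1 - rho^2) * e[t]
  }
  u
}
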