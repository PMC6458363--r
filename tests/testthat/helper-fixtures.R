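# small in-code fixtures shared across test files

tiny_table <- function(counts, sample_ids = NULL, otu_ids = NULL,
                       marker = "16S", compartment = "root") {
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- sprintf("P_%04d", seq_len(ncol(counts)))
  dimnames(counts) <- list(sample_ids, otu_ids)
  otu_table(counts, marker = marker, compartment = compartment)
}

# metadata tibble for hand-built tables; states recycled over samples
tiny_meta <- function(sample_ids, states,
                      sets = rep(1L, length(sample_ids)),
                      positions = seq_along(sample_ids),
                      dry_mass = rep(1, length(sample_ids))) {
  tibble::tibble(sample_id = sample_ids,
                 plant_state = if (is.factor(states)) states
                               else factor(states, levels = unique(states)),
                 sampling_set = as.integer(sets),
                 position = as.integer(positions),
                 dry_mass = dry_mass)
}

random_table <- function(n_samples, n_otus, seed, max_count = 50,
                         zero_frac = 0.4) {
  set.seed(seed)
  m <- matrix(rbinom(n_samples * n_otus, max_count, 0.5) *
                (runif(n_samples * n_otus) > zero_frac),
              n_samples, n_otus)
  tiny_table(m)
}

# Gaussian samples from a chain precision matrix (planted-graph data)
chain_gaussian <- function(n, p, seed, weight = 0.35) {
  set.seed(seed)
  om <- diag(p)
  for (i in seq_len(p - 1)) om[i, i + 1] <- om[i + 1, i] <- -weight
  x <- matrix(rnorm(n * p), n) %*% chol(solve(om))
  colnames(x) <- sprintf("V%02d", seq_len(p))
  rownames(x) <- sprintf("s%03d", seq_len(n))
  x
}

chain_edge_keys <- function(p) {
  paste(sprintf("V%02d", seq_len(p - 1)), sprintf("V%02d", 2:p), sep = "|")
}

edge_keys <- function(edges) {
  apply(cbind(pmin(edges$otu_a, edges$otu_b),
              pmax(edges$otu_a, edges$otu_b)), 1, paste, collapse = "|")
}

edge_f1 <- function(edges, truth_keys) {
  got <- edge_keys(edges)
  tp <- sum(got %in% truth_keys)
  if (length(got) + length(truth_keys) == 0) return(1)
  2 * tp / (length(got) + length(truth_keys))
}
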