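#' Zero out cells below a per-sample relative abundance threshold
#'
#' Removes likely PCR/sequencing carry-over: a cell is set to zero when its
#' read count is *strictly less* than `threshold` times the sample's total
#' read count, with the total taken before any cell is zeroed (single pass;
#' totals are not recomputed iteratively). Ties at exactly the threshold are
#' kept. The default 0.1% is the conventional per-sample cell filter for
#' amplicon matrices.
#'
#' @param table An `otu_tbl`.
#' @param threshold Fraction in (0, 1); default `0.001`.
#' @return The filtered `otu_tbl`, with a [preprocess_report()] attached
#'   recording the number of cells zeroed. Applying the filter twice warns:
#'   the pipeline applies it exactly once, and a second pass at the same
#'   threshold is not a no-op because totals shrink.
#' @export
filter_rare_cells <- function(table, threshold = 0.001) {
  stopifnot(is_otu_tbl(table))
  if (!(threshold > 0 && threshold < 1)) {
    abort("threshold must be in (0, 1)")
  }
  if (isTRUE(attr(table, "cell_filtered"))) {
    warn("relative-abundance cell filter already applied to this table")
  }
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  cut <- threshold * totals
  zero <- m < cut & m > 0        # strict <; cut computed from pre-filter totals
  m[zero] <- 0L
  out <- otu_table(m, marker = otu_marker(table),
                   compartment = otu_compartment(table))
  attr(out, "cell_filtered") <- TRUE
  set_report(out, list(step = "cell_filter", threshold = threshold,
                       cells_zeroed = sum(zero)))
}

#' Rarefy a count table to a fixed depth
#'
#' Each sample's reads are subsampled uniformly *without replacement*
#' (multivariate hypergeometric) down to `depth` reads; samples whose total
#' is below `depth` are discarded and listed in the report. Each sample
#' draws from its own RNG stream derived by hashing `(seed, sample_id)`, so
#' adding or dropping samples does not shift any other sample's draw.
#'
#' @param table An `otu_tbl`.
#' @param depth Target reads per sample (default 1000).
#' @param seed Integer seed governing all subsampling.
#' @return The rarefied `otu_tbl` (every row total equals `depth`), with a
#'   [preprocess_report()] listing dropped samples and their totals.
#' @export
rarefy <- function(table, depth = 1000, seed = 1) {
  stopifnot(is_otu_tbl(table))
  if (depth < 1) abort("depth must be >= 1")
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  keep <- totals >= depth
  dropped <- tibble(sample_id = rownames(m)[!keep],
                    total = unname(totals[!keep]))
  m <- m[keep, , drop = FALSE]
  for (s in seq_len(nrow(m))) {
    if (sum(m[s, ]) == depth) next   # subsample == population
    m[s, ] <- subsample_reads(m[s, ], depth,
                              stream_seed(seed, rownames(m)[s]))
  }
  out <- otu_table(m, marker = otu_marker(table),
                   compartment = otu_compartment(table))
  attr(out, "cell_filtered") <- attr(table, "cell_filtered")
  set_report(out, list(step = "rarefy", depth = depth, seed = seed,
                       samples_dropped = dropped),
             prev = preprocess_report(table))
}

# hypergeometric draw of `depth` reads from one sample's count vector
subsample_reads <- function(counts, depth, seed) {
  n_total <- sum(counts)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  idx <- sample.int(n_total, depth)
  cum <- cumsum(as.numeric(counts))
  bins <- findInterval(idx - 0.5, c(0, cum))
  as.integer(tabulate(bins, nbins = length(counts)))
}

# 31-bit polynomial hash of (seed, sample_id): per-sample RNG stream
stream_seed <- function(seed, sample_id) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (k in utf8ToInt(sample_id)) h <- (h * 131 + k) %% mod
  as.integer(h)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Keep OTUs detected in at least a minimum number of samples
#'
#' Co-abundance inference is unreliable for rare OTUs, so the network branch
#' of the pipeline retains only OTUs detected (count > 0) in `min_samples`
#' or more samples. The comparison is inclusive: an OTU present in exactly
#' `min_samples` samples is kept. Samples are never removed.
#'
#' @param table An `otu_tbl`.
#' @param min_samples Minimum number of samples with a nonzero count
#'   (default 30).
#' @return The column-filtered `otu_tbl`.
#' @export
filter_prevalence <- function(table, min_samples = 30) {
  stopifnot(is_otu_tbl(table))
  if (min_samples < 1) abort("min_samples must be >= 1")
  m <- as_count_matrix(table)
  keep <- colSums(m > 0) >= min_samples
  out <- otu_table(m[, keep, drop = FALSE], marker = otu_marker(table),
                   compartment = otu_compartment(table))
  attr(out, "cell_filtered") <- attr(table, "cell_filtered")
  attr(out, "markers") <- attr(table, "markers")
  set_report(out, list(step = "prevalence", min_samples = min_samples,
                       otus_removed = sum(!keep)),
             prev = preprocess_report(table))
}

#' Retrieve the preprocessing report attached to a table
#'
#' Each preprocessing step appends a record (step name, parameters, what was
#' removed) to the table's report, so the full filter -> rarefy ->
#' prevalence history of a matrix is inspectable and serializable.
#'
#' @param table An `otu_tbl` that has passed through preprocessing.
#' @return A list of step records (possibly `NULL` for a fresh table).
#' @export
preprocess_report <- function(table) attr(table, "preprocess_report")

set_report <- function(table, record, prev = NULL) {
  attr(table, "preprocess_report") <- c(prev, list(record))
  table
}

#' Run the fixed preprocessing pipeline on one table
#'
#' Applies, in the fixed order the downstream statistics assume:
#' relative-abundance cell filter, rarefaction to `depth` (dropping
#' shallower samples), and — only when `min_samples` is given — the
#' prevalence filter used by the network branch.
#'
#' @inheritParams filter_rare_cells
#' @inheritParams rarefy
#' @param min_samples If non-`NULL`, apply [filter_prevalence()] last.
#' @return The preprocessed `otu_tbl` with the cumulative report attached.
#' @export
preprocess <- function(table, threshold = 0.001, depth = 1000, seed = 1,
                       min_samples = NULL) {
  out <- rarefy(filter_rare_cells(table, threshold), depth = depth,
                seed = seed)
  if (!is.null(min_samples)) out <- filter_prevalence(out, min_samples)
  out
}
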