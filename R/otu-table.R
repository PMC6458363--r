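#' Construct a sample-by-OTU count table
#'
#' An `otu_tbl` is a tibble whose first column, `sample_id`, holds unique
#' sample identifiers and whose remaining columns hold non-negative integer
#' read counts, one column per OTU. The amplicon marker (`"16S"` for
#' prokaryotes, `"ITS"` for fungi) and the compartment the samples come from
#' (`"root"` or `"soil"`) travel with the table as attributes. By convention
#' OTU ids start with `"P_"` (prokaryote) or `"F_"` (fungus), but this is not
#' enforced.
#'
#' @param x A data frame with a `sample_id` column and integer count columns,
#'   or a numeric matrix with samples as rows (rownames = sample ids,
#'   colnames = OTU ids).
#' @param marker `"16S"` or `"ITS"`.
#' @param compartment `"root"` or `"soil"`.
#' @return A validated `otu_tbl`.
#' @examples
#' counts <- matrix(c(3L, 0L, 0L, 7L), 2, dimnames = list(c("s1", "s2"),
#'                  c("P_0001", "P_0002")))
#' otu_table(counts, marker = "16S", compartment = "root")
#' @export
otu_table <- function(x, marker = c("16S", "ITS"),
                      compartment = c("root", "soil")) {
  marker <- match.arg(marker)
  compartment <- match.arg(compartment)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input needs rownames (sample ids) and colnames (OTU ids)")
    }
    x <- bind_cols(tibble(sample_id = rownames(x)),
                   as_tibble(x, .name_repair = "minimal"))
  }
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("count table must have a 'sample_id' column")
  }
  x <- relocate(x, "sample_id")
  x$sample_id <- as.character(x$sample_id)
  out <- new_otu_tbl(x, marker, compartment)
  validate_otu_tbl(out)
}

new_otu_tbl <- function(x, marker, compartment) {
  structure(x,
            class = c("otu_tbl", "tbl_df", "tbl", "data.frame"),
            marker = marker, compartment = compartment)
}

validate_otu_tbl <- function(x) {
  sid <- x$sample_id
  if (anyDuplicated(sid)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  ids <- otu_ids(x)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate OTU ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (j in ids) {
    col <- x[[j]]
    if (!is.numeric(col)) {
      abort(paste0("counts for OTU '", j, "' are not numeric"))
    }
    bad <- which(is.na(col) | col < 0 | col != trunc(col))
    if (length(bad)) {
      abort(paste0("invalid count (negative, missing or non-integer) at ",
                   "sample '", sid[bad[1]], "', OTU '", j, "'"))
    }
    if (!is.integer(col)) x[[j]] <- as.integer(col)
  }
  x
}

#' @rdname otu_table
#' @export
is_otu_tbl <- function(x) inherits(x, "otu_tbl")

#' Accessors for `otu_tbl` metadata and counts
#'
#' @param x An `otu_tbl`.
#' @return `otu_ids()` and `sample_ids()` return character vectors;
#'   `otu_marker()` and `otu_compartment()` the stored labels;
#'   `as_count_matrix()` an integer matrix (rows = samples, columns = OTUs).
#' @export
otu_ids <- function(x) setdiff(names(x), "sample_id")

#' @rdname otu_ids
#' @export
sample_ids <- function(x) x$sample_id

#' @rdname otu_ids
#' @export
otu_marker <- function(x) attr(x, "marker")

#' @rdname otu_ids
#' @export
otu_compartment <- function(x) attr(x, "compartment")

#' @rdname otu_ids
#' @export
as_count_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x[otu_ids(x)]))
  storage.mode(m) <- "integer"
  rownames(m) <- x$sample_id
  m
}

#' Read and write sample-by-OTU count tables
#'
#' Count tables are stored as UTF-8 tab-separated text with a header row of
#' OTU ids, a first column named `sample_id`, and plain integer counts.
#' Files holding the transposed layout (rows = OTUs, columns = samples) are
#' supported only via the explicit `transposed` flag; the orientation is
#' never guessed from the contents, since auto-detection silently corrupts
#' square-ish matrices.
#'
#' @param path Path to a TSV file.
#' @inheritParams otu_table
#' @param transposed If `TRUE`, the file stores OTUs as rows and samples as
#'   columns (first column then holds OTU ids and the header holds sample
#'   ids).
#' @return `read_otu_table()` returns an `otu_tbl`; `write_otu_table()`
#'   returns `path` invisibly. Writing then reading reproduces counts,
#'   labels and their order exactly.
#' @export
read_otu_table <- function(path, marker = c("16S", "ITS"),
                           compartment = c("root", "soil"),
                           transposed = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("count table needs an id column and counts")
  if (transposed) {
    ids <- raw[[1]]
    m <- t(as.matrix(as.data.frame(raw[-1])))
    colnames(m) <- ids
    raw <- bind_cols(tibble(sample_id = rownames(m)),
                     as_tibble(m, .name_repair = "minimal"))
  } else {
    names(raw)[1] <- "sample_id"
  }
  for (j in setdiff(names(raw), "sample_id")) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) | v < 0 | v != trunc(v))
    if (length(bad)) {
      abort(paste0("invalid count in '", basename(path), "' at sample '",
                   raw$sample_id[bad[1]], "', OTU '", j, "': '",
                   raw[[j]][bad[1]], "'"))
    }
    raw[[j]] <- as.integer(v)
  }
  otu_table(raw, marker = marker, compartment = compartment)
}

#' @rdname read_otu_table
#' @param x An `otu_tbl` to write.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(is_otu_tbl(x))
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Merge prokaryote and fungal count tables from one compartment
#'
#' Joins two tables (typically 16S and ITS from the same compartment) on
#' their shared samples: the result keeps only samples present in *both*
#' inputs, with the OTU columns of `a` followed by those of `b` and counts
#' untouched. This is the input layout for cross-kingdom co-abundance
#' network inference.
#'
#' @param a,b `otu_tbl` objects with the same compartment and disjoint OTU
#'   id sets.
#' @return An `otu_tbl` with marker `"16S"` if either input is 16S (the
#'   marker label is only a tag once kingdoms are mixed); its
#'   `"markers"` attribute records both.
#' @export
merge_tables <- function(a, b) {
  stopifnot(is_otu_tbl(a), is_otu_tbl(b))
  if (!identical(otu_compartment(a), otu_compartment(b))) {
    abort("cannot merge tables from different compartments")
  }
  overlap <- intersect(otu_ids(a), otu_ids(b))
  if (length(overlap)) {
    abort(paste0("OTU ids present in both tables: ",
                 paste(head(overlap, 5), collapse = ", ")))
  }
  shared <- intersect(a$sample_id, b$sample_id)
  if (!length(shared)) abort("no samples shared between the two tables")
  ia <- a[match(shared, a$sample_id), , drop = FALSE]
  ib <- b[match(shared, b$sample_id), otu_ids(b), drop = FALSE]
  out <- otu_table(bind_cols(as_tibble(ia), as_tibble(ib)),
                   marker = otu_marker(a),
                   compartment = otu_compartment(a))
  attr(out, "markers") <- unique(c(otu_marker(a), otu_marker(b)))
  out
}

#' @export
print.otu_tbl <- function(x, ...) {
  cat(sprintf("# otu_tbl: %d samples x %d OTUs [%s, %s]\n",
              nrow(x), length(otu_ids(x)),
              otu_marker(x) %||% "?", otu_compartment(x) %||% "?"))
  NextMethod()
}
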