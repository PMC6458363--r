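#' Read per-sample metadata
#'
#' The metadata file is TSV with header
#' `sample_id  plant_state  sampling_set  position  dry_mass`. Plant state is
#' the field classification of each host individual: `green` (healthy),
#' `yellow` (intermediate) or `no_leaf` (heavily nematode-infected).
#' `sampling_set` identifies the planting line (1 or 2) and `position` the
#' index along that line (samples sit at 30 cm intervals). `dry_mass` is the
#' above-ground dry mass in grams and may be missing (`NA`).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id` (character), `plant_state`
#'   (factor with levels green, yellow, no_leaf), `sampling_set` (integer),
#'   `position` (integer) and `dry_mass` (double, `NA` allowed).
#' @export
read_sample_metadata <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_metadata(raw, src = basename(path))
}

#' Validate a sample metadata table
#'
#' @param meta A data frame with the columns documented in
#'   [read_sample_metadata()].
#' @param src Label used in error messages.
#' @return The validated tibble with typed columns.
#' @export
validate_metadata <- function(meta, src = "metadata") {
  meta <- as_tibble(meta)
  need <- c("sample_id", "plant_state", "sampling_set", "position")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(paste0(src, ": missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"dry_mass" %in% names(meta)) meta$dry_mass <- NA_character_
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    abort(paste0(src, ": duplicate sample ids"))
  }
  states <- c("green", "yellow", "no_leaf")
  bad <- setdiff(unique(as.character(meta$plant_state)), states)
  if (length(bad) || anyNA(meta$plant_state)) {
    abort(paste0(src, ": unknown plant_state value(s): ",
                 paste(bad, collapse = ", "),
                 " (expected green, yellow, no_leaf)"))
  }
  set <- suppressWarnings(as.integer(as.character(meta$sampling_set)))
  if (anyNA(set) || !all(set %in% c(1L, 2L))) {
    abort(paste0(src, ": sampling_set must be 1 or 2"))
  }
  pos <- suppressWarnings(as.integer(as.character(meta$position)))
  if (anyNA(pos)) abort(paste0(src, ": position must be an integer index"))
  dm <- suppressWarnings(as.numeric(as.character(meta$dry_mass)))
  if (any(!is.na(dm) & dm < 0)) abort(paste0(src, ": negative dry_mass"))
  tibble(sample_id = meta$sample_id,
         plant_state = factor(as.character(meta$plant_state),
                              levels = states),
         sampling_set = set,
         position = pos,
         dry_mass = dm)
}

#' @rdname read_sample_metadata
#' @param meta A validated metadata tibble.
#' @export
write_sample_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Read an OTU taxonomy table
#'
#' TSV with header `otu_id  phylum  class  order  family  genus  annotation`.
#' Missing ranks use the single sentinel `NA`; empty strings are normalized
#' to `NA` on read so the two never coexist.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per OTU.
#' @export
read_taxonomy <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  need <- c("otu_id", "phylum", "class", "order", "family", "genus",
            "annotation")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0(basename(path), ": missing taxonomy column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(raw$otu_id)) {
    abort(paste0(basename(path), ": duplicate otu_id"))
  }
  as_tibble(raw[need])
}

#' @rdname read_taxonomy
#' @param taxonomy A taxonomy tibble.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(taxonomy, path, na = "NA", progress = FALSE)
  invisible(path)
}

# match metadata rows to a table's samples, erroring on gaps
align_metadata <- function(table, meta) {
  idx <- match(sample_ids(table), meta$sample_id)
  if (anyNA(idx)) {
    abort(paste0("samples without metadata: ",
                 paste(head(sample_ids(table)[is.na(idx)], 5),
                       collapse = ", ")))
  }
  meta[idx, , drop = FALSE]
}
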