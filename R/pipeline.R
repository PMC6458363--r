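#' Assemble and validate a pipeline configuration
#'
#' A configuration names the input tables (one per marker x compartment),
#' the sample metadata, the output directory, the analysis thresholds and
#' the seeds. Defaults are the conventional constants of the analysis:
#' 0.1% cell filter, rarefaction depth 1000, prevalence 30, preference
#' cutoff 3, StARS instability budget 0.05, 100000 screen permutations and
#' 10000 PERMANOVA permutations. A seed is mandatory — the pipeline never
#' seeds itself from the clock.
#'
#' @param datasets Named list; each element a list with `path`, `marker`
#'   (`"16S"`/`"ITS"`) and `compartment` (`"root"`/`"soil"`).
#' @param metadata Path to the sample metadata TSV.
#' @param out_dir Output directory.
#' @param seed Integer master seed (mandatory).
#' @param taxonomy Optional path to a taxonomy TSV.
#' @param thresholds Named overrides of
#'   `list(cell = 0.001, depth = 1000, prevalence = 30, z_min = 3,
#'   beta = 0.05)`.
#' @param n_perm Named overrides of
#'   `list(screen = 1e5, permanova = 1e4, mantel = 999)`.
#' @param network Named overrides of `list(method = "mb",
#'   n_subsamples = 50, focal = character())`.
#' @param nmds_starts Random starts for NMDS (default 20).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(datasets, metadata, out_dir, seed,
                            taxonomy = NULL, thresholds = list(),
                            n_perm = list(), network = list(),
                            nmds_starts = 20) {
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  thr <- modifyList(list(cell = 0.001, depth = 1000, prevalence = 30,
                         z_min = 3, beta = 0.05), thresholds)
  np <- modifyList(list(screen = 1e5, permanova = 1e4, mantel = 999),
                   n_perm)
  net <- modifyList(list(method = "mb", n_subsamples = 50,
                         focal = character()), network)
  stopifnot(thr$cell > 0, thr$cell < 1, thr$depth >= 1,
            thr$prevalence >= 1, thr$z_min > 0,
            thr$beta > 0, thr$beta < 1,
            np$screen >= 1, np$permanova >= 1, np$mantel >= 1)
  if (!length(datasets) || is.null(names(datasets)) ||
      any(names(datasets) == "")) {
    abort("datasets must be a named list")
  }
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    if (!all(c("path", "marker", "compartment") %in% names(d))) {
      abort(paste0("dataset '", nm,
                   "' needs path, marker and compartment"))
    }
  }
  structure(list(datasets = datasets, metadata = metadata,
                 taxonomy = taxonomy, out_dir = out_dir,
                 thresholds = thr, n_perm = np, network = net,
                 nmds_starts = nmds_starts,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file with the same fields.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(datasets = y$datasets, metadata = y$metadata,
                  out_dir = y$out_dir, seed = y$seed,
                  taxonomy = y$taxonomy,
                  thresholds = y$thresholds %||% list(),
                  n_perm = y$n_perm %||% list(),
                  network = y$network %||% list(),
                  nmds_starts = y$nmds_starts %||% 20)
}

#' Run the full analysis pipeline
#'
#' For every configured dataset: read and validate the table, apply the
#' cell filter and rarefaction, run the preference screen (all scores plus
#' the `z >= z_min` shortlist), and the community statistics (PERMANOVA
#' with `sampling_set` then `plant_state`; a second PERMANOVA with
#' `sampling_set` then `dry_mass`; NMDS; Mantel correlogram on within-set
#' spatial distances). Then, per compartment with both a 16S and an ITS
#' table, merge them, apply the prevalence filter and infer the StARS
#' co-abundance network (plus focal neighborhoods when configured). All
#' results are written under `out_dir` as TSV/JSON along with a
#' `manifest.json` that records versions, seeds, parameters and
#' per-dataset counts; reruns with the same configuration are
#' byte-identical. Any stage failure aborts naming the stage and dataset.
#'
#' @param config A `pipeline_config`, or the path to a YAML file.
#' @return Invisibly, a list with the in-memory results per dataset and
#'   network, plus the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  thr <- config$thresholds

  meta <- stage("read_metadata", "all",
                read_sample_metadata(config$metadata))
  taxonomy <- if (!is.null(config$taxonomy)) {
    stage("read_taxonomy", "all", read_taxonomy(config$taxonomy))
  }

  results <- list(); manifest_ds <- list(); rarefied <- list()
  for (nm in names(config$datasets)) {
    ds <- config$datasets[[nm]]
    tab <- stage("read_table", nm,
                 read_otu_table(ds$path, marker = ds$marker,
                                compartment = ds$compartment,
                                transposed = isTRUE(ds$transposed)))
    prep <- stage("preprocess", nm,
                  preprocess(tab, threshold = thr$cell, depth = thr$depth,
                             seed = stream_seed(config$seed,
                                                paste0(nm, "/rarefy"))))
    rarefied[[nm]] <- prep
    write_otu_table(prep, file.path(out_dir,
                                    paste0(nm, ".rarefied.tsv")))

    pref <- stage("screen", nm,
                  preference_screen(prep, meta,
                                    n_perm = config$n_perm$screen,
                                    seed = stream_seed(config$seed,
                                                       paste0(nm, "/screen"))))
    hits <- screen_preferential(pref, z_min = thr$z_min)
    readr::write_tsv(pref, file.path(out_dir,
                                     paste0(nm, ".preference.tsv")),
                     progress = FALSE)
    readr::write_tsv(hits, file.path(out_dir,
                                     paste0(nm, ".preferential.tsv")),
                     progress = FALSE)

    comm <- stage("community", nm, {
      d <- bray_curtis(prep)
      sub_meta <- meta[meta$sample_id %in% sample_ids(prep), ]
      pmv <- permanova(d, sub_meta, c("sampling_set", "plant_state"),
                       n_perm = config$n_perm$permanova,
                       seed = stream_seed(config$seed,
                                          paste0(nm, "/permanova")))
      pmv_mass <- permanova(d, sub_meta, c("sampling_set", "dry_mass"),
                            n_perm = config$n_perm$permanova,
                            seed = stream_seed(config$seed,
                                               paste0(nm, "/permanova_mass")))
      ord <- nmds(d, n_starts = config$nmds_starts,
                  seed = stream_seed(config$seed, paste0(nm, "/nmds")))
      dsp <- spatial_distances(sub_meta)
      mc <- mantel_correlogram(d, dsp, n_perm = config$n_perm$mantel,
                               seed = stream_seed(config$seed,
                                                  paste0(nm, "/mantel")))
      list(permanova = pmv, permanova_mass = pmv_mass, nmds = ord,
           mantel = mc)
    })
    jsonlite::write_json(
      list(permanova = tidy(comm$permanova),
           permanova_dry_mass = tidy(comm$permanova_mass),
           nmds = list(stress = comm$nmds$stress,
                       points = comm$nmds$points),
           mantel = tidy(comm$mantel)),
      file.path(out_dir, paste0(nm, ".community.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")

    results[[nm]] <- list(table = prep, preference = pref,
                          preferential = hits, community = comm)
    manifest_ds[[nm]] <- list(
      path = ds$path, marker = ds$marker, compartment = ds$compartment,
      n_samples_raw = nrow(tab), n_samples = nrow(prep),
      n_otus = length(otu_ids(prep)),
      n_preferential = nrow(hits),
      preprocess = preprocess_report(prep))
  }

  networks <- list()
  comps <- unique(vapply(config$datasets, `[[`, "", "compartment"))
  for (cp in comps) {
    in_cp <- names(config$datasets)[
      vapply(config$datasets, `[[`, "", "compartment") == cp]
    mk <- vapply(config$datasets[in_cp], `[[`, "", "marker")
    if (!all(c("16S", "ITS") %in% mk)) next
    networks[[cp]] <- stage("network", cp, {
      merged <- merge_tables(rarefied[[in_cp[mk == "16S"][1]]],
                             rarefied[[in_cp[mk == "ITS"][1]]])
      merged <- filter_prevalence(merged, thr$prevalence)
      net <- infer_network(merged, method = config$network$method,
                           n_subsamples = config$network$n_subsamples,
                           beta = thr$beta,
                           seed = stream_seed(config$seed,
                                              paste0(cp, "/network")))
      readr::write_tsv(net$edges,
                       file.path(out_dir, paste0(cp, ".edges.tsv")),
                       progress = FALSE)
      focal <- intersect(config$network$focal, net$nodes)
      if (length(config$network$focal)) {
        nb <- extract_neighborhood(net, focal, sign = "positive",
                                   taxonomy = taxonomy)
        readr::write_tsv(nb,
                         file.path(out_dir,
                                   paste0(cp, ".neighborhoods.tsv")),
                         progress = FALSE)
      }
      net
    })
  }

  manifest <- list(
    package = "rhizonet",
    package_version = as.character(utils::packageVersion("rhizonet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = config$thresholds,
    n_perm = config$n_perm,
    datasets = manifest_ds,
    networks = lapply(networks, function(nt) {
      list(n_nodes = length(nt$nodes), n_edges = nrow(nt$edges),
           lambda_selected = nt$lambda_selected, method = nt$method,
           empty = nt$empty)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(datasets = results, networks = networks,
                 manifest = manifest))
}

stage <- function(name, dataset, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed for '", dataset,
                 "': ", conditionMessage(e)))
  })
}
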