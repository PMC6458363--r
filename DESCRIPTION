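Package: rhizonet
Title: Host-State Preference Screens and Co-Abundance Networks for
    Rhizosphere Microbiome Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired prokaryote (16S) and fungal (ITS)
    sample-by-OTU count tables from plant root and rhizosphere soil
    compartments. Implements table-level preprocessing (per-sample relative
    abundance cell filtering, seeded rarefaction without replacement,
    prevalence filtering), a permutation-null standardized preference index
    that screens OTUs for association with host plant states, community-level
    statistics (Bray-Curtis dissimilarity, sequential sums-of-squares
    PERMANOVA, non-metric multidimensional scaling, Mantel correlograms,
    rarefaction and accumulation curves), compositional co-abundance network
    inference via centered log-ratio transformed neighborhood selection or
    graphical lasso with StARS stability selection, and a Dirichlet-
    multinomial community simulator with planted ground truth for end-to-end
    calibration. Functions take and return tibbles and compose with the pipe;
    fitted objects provide tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
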