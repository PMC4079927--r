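Package: microdelta
Title: Paired-Intervention Microbiota-Host Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links diet-induced changes in gut microbiota composition to changes
    in host metabolic parameters over a paired before/after intervention.
    Builds a microbiota parameter set (rank-aggregated relative abundances,
    taxon ratios such as Firmicutes/Bacteroidetes and Prevotella/Bacteroides,
    and alpha-diversity indices), computes per-subject deltas, assembles a
    bipartite Kendall tau-b correlation network with connected-component
    summaries, and provides the multivariate confirmation layer (RV matrix
    correlation, NIPALS partial least squares with leave-one-out
    cross-validation and jackknife variable selection) together with a
    paired host-parameter test. A synthetic paired-cohort generator with
    planted, ground-truth associations makes every stage testable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    vegan,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
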