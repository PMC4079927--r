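# End-to-end orchestration: inputs -> community metrics -> deltas ->
# correlation network -> multivariate layer, with a provenance report.

#' Configure a pipeline run
#'
#' Either pass the five input paths (`counts_t0`, `counts_t29`, `taxonomy`,
#' `host_t0`, `host_t29`) or a [cohort_config()] via `simulate` to generate
#' the inputs in memory. The configuration is echoed verbatim into the run
#' report so a run can be reproduced from the report alone.
#'
#' @param counts_t0,counts_t29,taxonomy,host_t0,host_t29 Input file paths
#'   (ignored when `simulate` is given).
#' @param simulate Optional [cohort_config()].
#' @param depth Rarefaction depth (default 1000); `NULL` to skip.
#' @param delta_mode `"signed"` (default) or `"absolute_value"` for the
#'   microbiota deltas.
#' @param cutoff Kendall |tau| threshold for network edges (default 0.65).
#' @param min_n Minimum complete pairs per correlation (default 5).
#' @param alpha Level for the host test and jackknife selection.
#' @param pls_analyses Optional tibble with columns `response` (parameter id)
#'   and `predictors` (`"host"` or `"microbiota"`): one PLS model per row,
#'   fitted on the delta matrices.
#' @param seed Master seed for every stochastic step.
#' @param outdir Output directory (created if needed); `NULL` for no files.
#' @return List of class `run_config`.
#' @export
run_config <- function(counts_t0 = NULL, counts_t29 = NULL, taxonomy = NULL,
                       host_t0 = NULL, host_t29 = NULL, simulate = NULL,
                       depth = 1000, delta_mode = c("signed", "absolute_value"),
                       cutoff = 0.65, min_n = 5L, alpha = 0.05,
                       pls_analyses = NULL, seed = 1L, outdir = NULL) {
  delta_mode <- match.arg(delta_mode)
  if (is.null(simulate)) {
    paths <- list(counts_t0 = counts_t0, counts_t29 = counts_t29,
                  taxonomy = taxonomy, host_t0 = host_t0, host_t29 = host_t29)
    missing <- names(paths)[vapply(paths, is.null, logical(1))]
    if (length(missing)) {
      stop_config(paste0("missing input path(s): ", paste(missing, collapse = ", ")))
    }
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent)) {
      stop_config(paste0("input file(s) not found: ", paste(absent, collapse = ", ")))
    }
  } else {
    stopifnot(inherits(simulate, "cohort_config"))
    paths <- NULL
  }
  if (cutoff <= 0 || cutoff > 1) stop_config("`cutoff` must lie in (0, 1].")
  structure(list(paths = paths, simulate = simulate, depth = depth,
                 delta_mode = delta_mode, cutoff = cutoff,
                 min_n = as.integer(min_n), alpha = alpha,
                 pls_analyses = pls_analyses, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

stage <- function(name, warnings_env, code) {
  withCallingHandlers(
    tryCatch(code, error = function(e) {
      rlang::abort(paste0("[stage ", name, "] ", conditionMessage(e)), parent = e)
    }),
    warning = function(w) {
      warnings_env$log <- unique(c(warnings_env$log,
                                   paste0("[", name, "] ", conditionMessage(w))))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      warnings_env$log <- unique(c(warnings_env$log,
                                   paste0("[", name, "] ", trimws(conditionMessage(m)))))
      invokeRestart("muffleMessage")
    }
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: input loading (or cohort simulation), rarefied
#' community metrics (diversity, Bray-Curtis, UPGMA), microbiota/host
#' parameter assembly, paired deltas, pairwise Kendall correlations,
#' thresholding, bipartite network with connected components, the RV
#' coefficient between the genus-level and host delta blocks, configured PLS
#' models, and the univariate paired host test. Two runs with identical
#' configuration and inputs produce identical numeric outputs.
#'
#' @param config A [run_config()].
#' @return List with all stage results (`network`, `components`,
#'   `correlations`, `diversity`, `rv`, `pls`, `host_test`, ...) and
#'   `report` (the provenance report; written as JSON when `outdir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  wenv <- new.env(); wenv$log <- character()
  out <- list()

  inputs <- stage("input", wenv, {
    if (!is.null(config$simulate)) {
      sim <- simulate_cohort(config$simulate)
      sim
    } else {
      list(
        counts_t0 = read_abundance_table(config$paths$counts_t0),
        counts_t29 = read_abundance_table(config$paths$counts_t29),
        taxonomy = read_taxonomy(config$paths$taxonomy),
        host_t0 = read_host_table(config$paths$host_t0),
        host_t29 = read_host_table(config$paths$host_t29)
      )
    }
  })

  metrics <- stage("community_metrics", wenv, {
    counts_all <- dplyr::bind_rows(
      dplyr::mutate(inputs$counts_t0, .tp = "t0"),
      dplyr::mutate(inputs$counts_t29, .tp = "t29")
    )
    tp <- counts_all$.tp
    counts_all$.tp <- NULL
    counts_all[[1]] <- paste0(counts_all[[1]], "_", tp)
    rr <- if (is.null(config$depth)) counts_all else {
      rarefy(counts_all, config$depth, seed = derive_seed(config$seed, 201L))
    }
    bc <- bray_curtis(rr)
    list(diversity = diversity_indices(rr), bray_curtis = bc,
         upgma = if (nrow(bc) >= 2) upgma(bc) else NULL)
  })

  mpair <- stage("microbiota_parameters", wenv, {
    build_microbiota_parameters(inputs$counts_t0, inputs$counts_t29,
                                inputs$taxonomy, depth = config$depth,
                                seed = derive_seed(config$seed, 301L))
  })
  hpair <- stage("host_parameters", wenv,
                 host_parameter_pair(inputs$host_t0, inputs$host_t29))

  dM <- stage("delta", wenv, delta_microbiota(mpair, mode = config$delta_mode))
  dP <- stage("delta", wenv, delta_host(hpair))

  corr <- stage("correlations", wenv,
                pairwise_correlations(dM, dP, min_n = config$min_n))
  kept <- stage("network", wenv, threshold_edges(corr, cutoff = config$cutoff))
  network <- stage("network", wenv, build_network(kept, mpair$parameter_info))
  comps <- stage("network", wenv, connected_components(network))
  comp_rep <- stage("network", wenv, component_report(comps, network))

  rv <- stage("rv", wenv, {
    mg <- tbl_to_matrix(dM)
    genus_cols <- grep("^g__", colnames(mg), value = TRUE)
    mg <- mg[, genus_cols, drop = FALSE]
    ph <- tbl_to_matrix(dP)
    shared <- intersect(rownames(mg), rownames(ph))
    mg <- mg[shared, apply(mg[shared, , drop = FALSE], 2, function(c) !anyNA(c) && stats::sd(c) > 0), drop = FALSE]
    ph <- ph[shared, apply(ph[shared, , drop = FALSE], 2, function(c) !anyNA(c) && stats::sd(c) > 0), drop = FALSE]
    rv_coefficient(mg, ph)
  })

  pls <- stage("pls", wenv, {
    if (is.null(config$pls_analyses)) NULL else {
      purrr::pmap(config$pls_analyses, function(response, predictors, ...) {
        Mm <- tbl_to_matrix(dM); Pm <- tbl_to_matrix(dP)
        if (predictors == "host") {
          y_src <- if (response %in% colnames(Mm)) Mm else Pm
          x <- Pm
        } else {
          y_src <- if (response %in% colnames(Pm)) Pm else Mm
          x <- Mm
        }
        if (!response %in% colnames(y_src)) {
          rlang::abort(paste0("PLS response not found: ", response))
        }
        y <- y_src[, response]
        x <- x[, colnames(x) != response, drop = FALSE]
        ok <- stats::complete.cases(cbind(y, x))
        x <- x[ok, apply(x[ok, , drop = FALSE], 2, function(c) stats::sd(c) > 0), drop = FALSE]
        fit <- pls_analysis(x, y[ok], max_components = min(3, sum(ok) - 2),
                            alpha = config$alpha)
        fit$response <- response
        fit$predictors <- predictors
        fit
      })
    }
  })

  host_test <- stage("host_test", wenv,
                     paired_host_test(inputs$host_t0, inputs$host_t29,
                                      alpha = config$alpha))

  corr_report <- attr(corr, "report")
  report <- list(
    package_version = as.character(utils::packageVersion("microdelta")),
    r_version = as.character(getRversion()),
    config = serialize_config(config),
    counts = list(
      n_subjects = nrow(inputs$counts_t0),
      n_taxa = ncol(inputs$counts_t0) - 1L,
      n_host_parameters = ncol(inputs$host_t0) - 1L,
      n_microbiota_parameters = ncol(mpair$values_t0) - 1L,
      dropped_subjects = mpair$dropped_subjects,
      n_candidate_pairs = corr_report$n_candidate,
      n_defined_pairs = corr_report$n_defined,
      n_excluded_pairs = corr_report$n_excluded,
      n_edges = nrow(network$edges),
      n_nodes = nrow(network$nodes),
      n_components = nrow(comps$summary)
    ),
    warnings = wenv$log
  )

  out <- list(inputs = inputs, metrics = metrics,
              microbiota_pair = mpair, host_pair = hpair,
              delta_microbiota = dM, delta_host = dP,
              correlations = corr, network = network, components = comps,
              component_report = comp_rep, rv = rv, pls = pls,
              host_test = host_test, report = report)

  if (!is.null(config$outdir)) write_bundle(out, config)
  out
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulate)) cfg$simulate <- unclass(cfg$simulate)
  cfg
}

write_bundle <- function(result, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outdir, f)
  readr::write_tsv(result$metrics$diversity, p("diversity.tsv"))
  write_distance_matrix(result$metrics$bray_curtis, p("bray_curtis.tsv"))
  if (!is.null(result$metrics$upgma)) write_newick(result$metrics$upgma, p("upgma.nwk"))
  readr::write_tsv(result$delta_microbiota, p("delta_microbiota.tsv"))
  readr::write_tsv(result$delta_host, p("delta_host.tsv"))
  corr <- dplyr::mutate(result$correlations,
                        kept = !is.na(.data$tau) &
                          abs(.data$tau) >= config$cutoff - 1e-12)
  readr::write_tsv(corr, p("correlations.tsv"))
  if (nrow(result$network$edges)) {
    write_graphml(result$network, p("network.graphml"))
    write_sif(result$network, p("network.sif"), p("network_edges.tsv"))
  }
  readr::write_tsv(result$components$summary, p("components.tsv"))
  jsonlite::write_json(
    lapply(seq_len(nrow(result$component_report)), function(i) {
      r <- result$component_report[i, ]
      list(component_id = r$component_id, n_nodes = r$n_nodes, n_edges = r$n_edges,
           microbial_nodes = r$microbial_nodes[[1]], host_nodes = r$host_nodes[[1]],
           phylum_breakdown = as.list(r$phylum_breakdown[[1]]),
           n_positive = r$n_positive, n_negative = r$n_negative)
    }),
    p("component_report.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(result$host_test, p("host_test.tsv"))
  if (!is.null(result$pls)) {
    for (fit in result$pls) {
      slug <- gsub("[^A-Za-z0-9]+", "_", fit$response)
      readr::write_tsv(fit$jackknife, p(paste0("pls_", slug, "_coefficients.tsv")))
    }
  }
  jsonlite::write_json(result$report, p("run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(config$outdir)
}
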