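# Core procedure: microbiota parameter set, paired deltas, pairwise Kendall
# correlations, thresholding, bipartite network and connected components.

#' Build the microbiota parameter set at both time points
#'
#' Assembles the parameter set M used for delta-correlation analysis:
#' relative abundances at every taxonomic rank (phylum through genus, ids
#' prefixed `p__`/`c__`/`o__`/`f__`/`g__`), the community ratios
#' Firmicutes/Bacteroidetes, Prevotella/Bacteroides and Bacteroides/Prevotella,
#' and the alpha-diversity indices (Shannon, Simpson, richness), computed
#' identically at both time points. Counts are rarefied to `depth` first
#' (set `depth = NULL` to skip when libraries are already even); subjects
#' dropped at either time point are dropped at both.
#'
#' @param counts_t0,counts_t29 Count tibbles with matching subject ids.
#' @param taxonomy Taxonomy tibble covering every taxon column.
#' @param depth Rarefaction depth (default 1000); `NULL` skips rarefaction.
#' @param seed Seed for rarefaction.
#' @param ratios,indices Include ratio / diversity parameters (default TRUE).
#' @return List of class `param_pair` with `values_t0`, `values_t29`
#'   (tibbles, first column `subject_id`), `parameter_info` (tibble:
#'   `param_id`, `kind`, `rank`, `taxon`, `phylum`), `kind = "microbial"`,
#'   and `dropped_subjects`.
#' @export
build_microbiota_parameters <- function(counts_t0, counts_t29, taxonomy,
                                        depth = 1000, seed = 1L,
                                        ratios = TRUE, indices = TRUE) {
  ids0 <- as.character(counts_t0[[1]])
  ids29 <- as.character(counts_t29[[1]])
  odd <- c(setdiff(ids0, ids29), setdiff(ids29, ids0))
  if (length(odd)) {
    rlang::abort(paste0("subject(s) present at only one time point: ",
                        paste(unique(odd), collapse = ", ")))
  }

  dropped <- character()
  if (!is.null(depth)) {
    r0 <- rarefy(counts_t0, depth, seed = derive_seed(seed, 101L))
    r29 <- rarefy(counts_t29, depth, seed = derive_seed(seed, 102L))
    dropped <- union(attr(r0, "dropped"), attr(r29, "dropped"))
    keep <- setdiff(ids0, dropped)
    r0 <- r0[as.character(r0[[1]]) %in% keep, ]
    r29 <- r29[as.character(r29[[1]]) %in% keep, ]
  } else {
    r0 <- counts_t0
    r29 <- counts_t29
  }

  one_timepoint <- function(cnt) {
    vals <- list()
    info <- list()
    for (rk in taxonomic_ranks) {
      agg <- aggregate_by_rank(cnt, taxonomy, rk)
      rel <- relative_abundance(agg)
      prefix <- paste0(substr(rk, 1, 1), "__")
      taxa <- names(rel)[-1]
      names(rel)[-1] <- paste0(prefix, taxa)
      vals[[rk]] <- rel
      ph <- if (rk == "phylum") taxa else taxonomy$phylum[match(taxa, taxonomy[[rk]])]
      info[[rk]] <- tibble::tibble(param_id = paste0(prefix, taxa), kind = "abundance",
                                   rank = rk, taxon = taxa, phylum = ph)
    }
    out <- purrr::reduce(vals, dplyr::left_join, by = names(cnt)[1])

    if (ratios) {
      phy <- vals$phylum; gen <- vals$genus
      ratio_defs <- list(
        c("ratio__Firmicutes_Bacteroidetes", "p__Firmicutes", "p__Bacteroidetes", "phylum"),
        c("ratio__Prevotella_Bacteroides", "g__Prevotella", "g__Bacteroides", "genus"),
        c("ratio__Bacteroides_Prevotella", "g__Bacteroides", "g__Prevotella", "genus")
      )
      for (rd in ratio_defs) {
        src <- if (rd[4] == "phylum") phy else gen
        if (all(c(rd[2], rd[3]) %in% names(src))) {
          rr <- suppressWarnings(taxon_ratio(src, rd[2], rd[3]))
          out[[rd[1]]] <- rr$ratio
        } else {
          out[[rd[1]]] <- NA_real_
        }
        info[[rd[1]]] <- tibble::tibble(param_id = rd[1], kind = "ratio",
                                        rank = NA_character_, taxon = NA_character_,
                                        phylum = NA_character_)
      }
    }

    if (indices) {
      div <- diversity_indices(cnt)
      for (ix in c("shannon", "simpson", "richness")) {
        out[[paste0("div__", ix)]] <- as.numeric(div[[ix]])
        info[[paste0("div__", ix)]] <- tibble::tibble(param_id = paste0("div__", ix),
                                                      kind = "diversity",
                                                      rank = NA_character_,
                                                      taxon = NA_character_,
                                                      phylum = NA_character_)
      }
    }
    names(out)[1] <- "subject_id"
    list(values = out, info = dplyr::bind_rows(info))
  }

  a <- one_timepoint(r0)
  b <- one_timepoint(r29)
  stopifnot(identical(names(a$values), names(b$values)))
  structure(
    list(values_t0 = a$values, values_t29 = b$values,
         parameter_info = a$info, kind = "microbial",
         dropped_subjects = dropped),
    class = "param_pair"
  )
}

#' Pair host-parameter tables
#'
#' Aligns two host-parameter tables on shared subject ids into the same
#' paired structure used for microbiota parameters.
#'
#' @param host_t0,host_t29 Tibbles (first column subject id, numeric columns).
#' @return `param_pair` with `kind = "host"`.
#' @export
host_parameter_pair <- function(host_t0, host_t29) {
  ids0 <- as.character(host_t0[[1]])
  ids29 <- as.character(host_t29[[1]])
  odd <- c(setdiff(ids0, ids29), setdiff(ids29, ids0))
  if (length(odd)) {
    rlang::abort(paste0("subject(s) present at only one time point: ",
                        paste(unique(odd), collapse = ", ")))
  }
  if (!identical(sort(names(host_t0)), sort(names(host_t29)))) {
    rlang::abort("host tables must share the same parameter columns.")
  }
  host_t29 <- host_t29[match(ids0, ids29), names(host_t0)]
  names(host_t0)[1] <- names(host_t29)[1] <- "subject_id"
  structure(
    list(values_t0 = tibble::as_tibble(host_t0),
         values_t29 = tibble::as_tibble(host_t29),
         parameter_info = tibble::tibble(param_id = names(host_t0)[-1], kind = "host",
                                         rank = NA_character_, taxon = NA_character_,
                                         phylum = NA_character_),
         kind = "host", dropped_subjects = character()),
    class = "param_pair"
  )
}

#' Per-subject change in microbiota parameters
#'
#' Arithmetic (non-relative) difference of each microbiota parameter across
#' the intervention: `delta = M_t29 - M_t0` (`mode = "signed"`, default) or
#' its magnitude (`mode = "absolute_value"`). Missing values propagate.
#'
#' @param pair A microbial `param_pair`.
#' @param mode `"signed"` or `"absolute_value"`.
#' @return Tibble of deltas (first column `subject_id`) with attributes
#'   `kind = "microbial_delta"` and `mode`.
#' @export
delta_microbiota <- function(pair, mode = c("signed", "absolute_value")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pair, "param_pair"))
  m0 <- tbl_to_matrix(pair$values_t0)
  m29 <- tbl_to_matrix(pair$values_t29)
  d <- m29 - m0
  if (mode == "absolute_value") d <- abs(d)
  out <- matrix_to_tbl(d, "subject_id")
  attr(out, "kind") <- "microbial_delta"
  attr(out, "mode") <- mode
  out
}

#' Per-subject relative change in host parameters
#'
#' `delta = (P_t29 - P_t0) / P_t0`. A zero baseline makes the relative change
#' undefined: the entry becomes `NA` and a warning reports how many cells were
#' affected. Missing inputs propagate.
#'
#' @param pair A host `param_pair`.
#' @return Tibble of relative deltas with attribute `kind = "host_relative_delta"`.
#' @export
delta_host <- function(pair) {
  stopifnot(inherits(pair, "param_pair"))
  p0 <- tbl_to_matrix(pair$values_t0)
  p29 <- tbl_to_matrix(pair$values_t29)
  zero <- !is.na(p0) & p0 == 0
  d <- (p29 - p0) / p0
  d[zero] <- NA_real_
  if (any(zero)) {
    rlang::warn(paste0("delta_host: ", sum(zero),
                       " zero-baseline cell(s) set to NA (relative change undefined)."))
  }
  out <- matrix_to_tbl(d, "subject_id")
  attr(out, "kind") <- "host_relative_delta"
  out
}

#' All pairwise microbiota-host delta correlations
#'
#' Kendall tau-b between every (microbial delta, host delta) parameter pair on
#' pairwise-complete subjects. Pairs with fewer than `min_n` complete pairs or
#' a constant vector are excluded (tau `NA`, reason recorded) rather than
#' reported as zero.
#'
#' @param delta_m Microbial delta tibble (from [delta_microbiota()]).
#' @param delta_p Host delta tibble (from [delta_host()]).
#' @param min_n Minimum complete pairs per correlation (default 5).
#' @return Tibble with `microbial_param`, `host_param`, `tau`, `n_pairs`,
#'   `excluded_reason`; attribute `"report"` tallies exclusions.
#' @export
pairwise_correlations <- function(delta_m, delta_p, min_n = 5L) {
  m <- tbl_to_matrix(delta_m)
  p <- tbl_to_matrix(delta_p)
  shared <- intersect(rownames(m), rownames(p))
  if (length(shared) == 0) rlang::abort("no shared subjects between delta tables.")
  m <- m[shared, , drop = FALSE]
  p <- p[shared, , drop = FALSE]

  grid <- tidyr::expand_grid(microbial_param = colnames(m), host_param = colnames(p))
  res <- purrr::pmap_dfr(grid, function(microbial_param, host_param) {
    k <- kendall_tau(m[, microbial_param], p[, host_param], min_n = min_n)
    tibble::tibble(microbial_param = microbial_param, host_param = host_param,
                   tau = k$tau, n_pairs = k$n_pairs, excluded_reason = k$reason)
  })
  attr(res, "report") <- list(
    n_candidate = nrow(res),
    n_defined = sum(!is.na(res$tau)),
    n_excluded = sum(!is.na(res$excluded_reason)),
    excluded_by_reason = table(res$excluded_reason[!is.na(res$excluded_reason)])
  )
  res
}

#' Threshold correlation edges on |tau|
#'
#' Keeps pairs with `|tau| >= cutoff` (inclusive, with 1e-12 float slack).
#'
#' @param edges Correlation tibble from [pairwise_correlations()].
#' @param cutoff Threshold in (0, 1] (default 0.65).
#' @return Filtered edge tibble with a `sign` column.
#' @export
threshold_edges <- function(edges, cutoff = 0.65) {
  if (cutoff <= 0 || cutoff > 1) rlang::abort("`cutoff` must lie in (0, 1].")
  kept <- dplyr::filter(edges, !is.na(.data$tau), abs(.data$tau) >= cutoff - 1e-12)
  dplyr::mutate(kept, sign = ifelse(.data$tau >= 0, 1L, -1L))
}

#' Build the bipartite microbiota-host correlation network
#'
#' Nodes are exactly the parameters incident to at least one retained edge,
#' typed `microbial` or `host`; edges carry tau, its sign and the number of
#' complete pairs used. Microbial nodes are annotated with rank/lineage when
#' `parameter_info` is supplied.
#'
#' @param edges Thresholded edge tibble ([threshold_edges()]).
#' @param parameter_info Optional `parameter_info` tibble from
#'   [build_microbiota_parameters()] for node annotation.
#' @return Object of class `bipartite_network`: list with `nodes` and `edges`
#'   tibbles.
#' @export
build_network <- function(edges, parameter_info = NULL) {
  both <- intersect(unique(edges$microbial_param), unique(edges$host_param))
  if (length(both)) {
    rlang::abort(paste0("parameter id(s) appear on both sides (non-bipartite): ",
                        paste(both, collapse = ", ")))
  }
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = unique(edges$microbial_param), type = "microbial"),
    tibble::tibble(id = unique(edges$host_param), type = "host")
  )
  if (!is.null(parameter_info)) {
    nodes <- dplyr::left_join(nodes,
                              dplyr::select(parameter_info, id = "param_id",
                                            "kind", "rank", "taxon", "phylum"),
                              by = "id")
  }
  structure(list(nodes = nodes, edges = tibble::as_tibble(edges)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("Bipartite microbiota-host correlation network\n")
  cat("  nodes:", nrow(x$nodes),
      sprintf("(%d microbial, %d host)\n",
              sum(x$nodes$type == "microbial"), sum(x$nodes$type == "host")))
  cat("  edges:", nrow(x$edges),
      sprintf("(%d positive, %d negative)\n",
              sum(x$edges$tau >= 0), sum(x$edges$tau < 0)))
  invisible(x)
}

network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = network$edges[, c("microbial_param", "host_param", "tau", "n_pairs")],
    directed = FALSE,
    vertices = network$nodes
  )
}

#' Connected components of the correlation network
#'
#' Partitions the network into its maximal connected sub-networks, sorted by
#' decreasing node count, then edge count, then smallest node id. Components
#' with a single edge are single correlations; multi-edge components group
#' related parameters.
#'
#' @param network A `bipartite_network`.
#' @return Object of class `network_components`: list with `summary` (one row
#'   per component: `component_id`, `n_nodes`, `n_edges`, `n_microbial`,
#'   `n_host`) and `membership` (`node_id`, `type`, `component_id`).
#' @export
connected_components <- function(network) {
  if (nrow(network$edges) == 0) {
    return(structure(list(
      summary = tibble::tibble(component_id = integer(), n_nodes = integer(),
                               n_edges = integer(), n_microbial = integer(),
                               n_host = integer()),
      membership = tibble::tibble(node_id = character(), type = character(),
                                  component_id = integer())
    ), class = "network_components"))
  }
  g <- network_igraph(network)
  comp <- igraph::components(g)
  memb <- tibble::tibble(node_id = names(comp$membership),
                         raw = as.integer(comp$membership))
  memb <- dplyr::left_join(memb, network$nodes[, c("id", "type")],
                           by = c(node_id = "id"))
  edge_comp <- memb$raw[match(network$edges$microbial_param, memb$node_id)]
  summ <- memb %>%
    dplyr::group_by(.data$raw) %>%
    dplyr::summarise(n_nodes = dplyr::n(),
                     n_microbial = sum(.data$type == "microbial"),
                     n_host = sum(.data$type == "host"),
                     min_id = min(.data$node_id), .groups = "drop")
  summ$n_edges <- as.integer(table(factor(edge_comp, levels = summ$raw)))
  summ <- summ[order(-summ$n_nodes, -summ$n_edges, summ$min_id), ]
  summ$component_id <- seq_len(nrow(summ))
  memb$component_id <- summ$component_id[match(memb$raw, summ$raw)]
  structure(list(
    summary = tibble::as_tibble(summ[, c("component_id", "n_nodes", "n_edges",
                                         "n_microbial", "n_host")]),
    membership = memb[order(memb$component_id, memb$node_id),
                      c("node_id", "type", "component_id")]
  ), class = "network_components")
}

#' @export
print.network_components <- function(x, ...) {
  cat("Network components:", nrow(x$summary), "\n")
  print(x$summary, n = 10)
  invisible(x)
}

#' Structured per-component summary
#'
#' For each connected component: its node ids by type, the phylum breakdown of
#' the microbial abundance nodes, and the tally of positive/negative edges.
#'
#' @param components A `network_components` object.
#' @param network The `bipartite_network` the components came from.
#' @return Tibble, one row per component, with list-columns `microbial_nodes`,
#'   `host_nodes`, `phylum_breakdown` and counts `n_positive`, `n_negative`.
#' @export
component_report <- function(components, network) {
  if (nrow(components$summary) == 0) {
    return(tibble::tibble(component_id = integer(), n_nodes = integer(),
                          n_edges = integer(), microbial_nodes = list(),
                          host_nodes = list(), phylum_breakdown = list(),
                          n_positive = integer(), n_negative = integer()))
  }
  memb <- components$membership
  edges <- network$edges
  edges$component_id <- memb$component_id[match(edges$microbial_param, memb$node_id)]
  nodes <- network$nodes
  purrr::map_dfr(components$summary$component_id, function(cid) {
    nd <- memb[memb$component_id == cid, ]
    ed <- edges[edges$component_id == cid, ]
    mic <- nd$node_id[nd$type == "microbial"]
    phyla <- nodes$phylum[match(mic, nodes$id)]
    tibble::tibble(
      component_id = cid,
      n_nodes = nrow(nd), n_edges = nrow(ed),
      microbial_nodes = list(mic),
      host_nodes = list(nd$node_id[nd$type == "host"]),
      phylum_breakdown = list(sort(table(phyla[!is.na(phyla)]), decreasing = TRUE)),
      n_positive = sum(ed$tau >= 0), n_negative = sum(ed$tau < 0)
    )
  })
}

#' Export a network as GraphML
#'
#' @param network A `bipartite_network`.
#' @param path Output file path.
#' @export
write_graphml <- function(network, path) {
  g <- network_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network in Cytoscape SIF format plus edge attributes
#'
#' Writes `<microbial> pos|neg <host>` lines to `path` and, when
#' `attr_path` is given, a tab-separated edge-attribute table
#' (tau and n_pairs per edge).
#'
#' @param network A `bipartite_network`.
#' @param path SIF output path.
#' @param attr_path Optional edge-attribute TSV path.
#' @export
write_sif <- function(network, path, attr_path = NULL) {
  e <- network$edges
  rel <- ifelse(e$tau >= 0, "pos", "neg")
  writeLines(paste(e$microbial_param, rel, e$host_param, sep = "\t"), path)
  if (!is.null(attr_path)) {
    readr::write_tsv(dplyr::transmute(e, source = .data$microbial_param,
                                      interaction = rel, target = .data$host_param,
                                      tau = .data$tau, n_pairs = .data$n_pairs),
                     attr_path)
  }
  invisible(path)
}
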