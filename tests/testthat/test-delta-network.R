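test_that("the microbiota parameter set follows the construction rule", {
  sim <- tiny_cohort()
  mp <- build_microbiota_parameters(sim$counts_t0, sim$counts_t29, sim$taxonomy,
                                    depth = NULL)
  ids <- names(mp$values_t0)[-1]
  n_rank_cols <- sum(vapply(c("phylum", "class", "order", "family", "genus"),
                            function(rk) dplyr::n_distinct(sim$taxonomy[[rk]]),
                            numeric(1)))
  expect_equal(length(ids), n_rank_cols + 3 + 3)  # ranks + 3 ratios + 3 indices
  expect_true(all(c("ratio__Firmicutes_Bacteroidetes", "ratio__Prevotella_Bacteroides",
                    "ratio__Bacteroides_Prevotella", "div__shannon", "div__simpson",
                    "div__richness") %in% ids))
  expect_true(any(startsWith(ids, "g__")) && any(startsWith(ids, "p__")))
  expect_equal(nrow(mp$parameter_info), length(ids))

  # identical inputs at both time points give identical parameter values
  mp2 <- build_microbiota_parameters(sim$counts_t0, sim$counts_t0, sim$taxonomy,
                                     depth = NULL)
  expect_equal(mp2$values_t0, mp2$values_t29)
})

test_that("ratio parameters are missing-flagged when the index taxa are absent", {
  tx <- tibble::tibble(taxon_id = c("GenusA", "GenusB"),
                       phylum = c("Firmicutes", "Proteobacteria"),
                       class = c("F_c", "P_c"), order = c("F_o", "P_o"),
                       family = c("F_f", "P_f"), genus = c("GenusA", "GenusB"))
  cnt <- tibble::tibble(sample_id = c("S1", "S2"), GenusA = c(10, 5), GenusB = c(2, 6))
  mp <- build_microbiota_parameters(cnt, cnt, tx, depth = NULL)
  expect_true(all(is.na(mp$values_t0$ratio__Prevotella_Bacteroides)))
  expect_true(all(is.na(mp$values_t0$ratio__Firmicutes_Bacteroidetes)))
})

test_that("subject mismatches between time points are reported by id", {
  sim <- tiny_cohort()
  expect_error(build_microbiota_parameters(sim$counts_t0[-1, ], sim$counts_t29,
                                           sim$taxonomy),
               "S01")
  expect_error(host_parameter_pair(sim$host_t0[-2, ], sim$host_t29), "S02")
})

test_that("delta transforms implement signed, absolute and relative change", {
  pair <- structure(list(
    values_t0 = tibble::tibble(subject_id = c("a", "b"), x = c(0.10, 0.25)),
    values_t29 = tibble::tibble(subject_id = c("a", "b"), x = c(0.25, 0.10))
  ), class = "param_pair")
  expect_equal(delta_microbiota(pair)$x, c(0.15, -0.15))
  expect_equal(delta_microbiota(pair, "absolute_value")$x, c(0.15, 0.15))

  hpair <- host_parameter_pair(
    tibble::tibble(subject_id = c("a", "b", "c"), p = c(100, 80, 0)),
    tibble::tibble(subject_id = c("a", "b", "c"), p = c(120, 60, 5))
  )
  expect_warning(dh <- delta_host(hpair), "zero-baseline")
  expect_equal(dh$p, c(0.20, -0.25, NA))
})

test_that("pairwise correlations cover all pairs and exclude what they must", {
  dM <- tibble::tibble(subject_id = sprintf("S%d", 1:8),
                       m1 = 1:8, m2 = c(2, 1, 4, 3, 6, 5, 8, 7), m3 = rep(1, 8))
  dP <- tibble::tibble(subject_id = sprintf("S%d", 1:8),
                       h1 = (1:8)^2, h2 = c(rnorm(5), NA, NA, NA))
  co <- pairwise_correlations(dM, dP, min_n = 6)
  expect_equal(nrow(co), 6)  # all candidate pairs reported
  expect_equal(co$tau[co$microbial_param == "m1" & co$host_param == "h1"], 1)
  expect_true(all(is.na(co$tau[co$microbial_param == "m3"])))
  expect_true(all(co$excluded_reason[co$host_param == "h2"] == "too_few_pairs"))
  rep <- attr(co, "report")
  expect_equal(rep$n_candidate, 6)
  expect_equal(rep$n_defined + rep$n_excluded, 6)
  expect_error(pairwise_correlations(dM,
    tibble::tibble(subject_id = "X1", h = 1), min_n = 2), "no shared subjects")
})

test_that("edge thresholding is inclusive at the cutoff and uses |tau|", {
  edges <- tibble::tibble(microbial_param = paste0("m", 1:3), host_param = "h",
                          tau = c(0.65, -0.80, 0.60), n_pairs = 10,
                          excluded_reason = NA_character_)
  kept <- threshold_edges(edges, 0.65)
  expect_setequal(kept$microbial_param, c("m1", "m2"))
  expect_equal(kept$sign[kept$microbial_param == "m2"], -1L)
  # monotone: raising the cutoff never adds edges
  cuts <- seq(0.1, 1, by = 0.1)
  set.seed(21)
  rnd <- tibble::tibble(microbial_param = sample(paste0("m", 1:10), 40, TRUE),
                        host_param = sample(paste0("h", 1:6), 40, TRUE),
                        tau = runif(40, -1, 1), n_pairs = 10,
                        excluded_reason = NA_character_)
  ns <- vapply(cuts, function(ct) nrow(threshold_edges(rnd, ct)), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("network construction is strictly bipartite with incident-only nodes", {
  e0 <- threshold_edges(tibble::tibble(microbial_param = character(),
                                       host_param = character(), tau = numeric(),
                                       n_pairs = integer(),
                                       excluded_reason = character()), 0.65)
  empty <- build_network(e0)
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(connected_components(empty)$summary), 0)

  one <- build_network(tibble::tibble(microbial_param = "g__A", host_param = "h1",
                                      tau = 0.8, n_pairs = 10, sign = 1L))
  expect_equal(nrow(one$nodes), 2)
  expect_equal(nrow(connected_components(one)$summary), 1)

  # node count identity: incident microbial + incident host
  sim <- tiny_cohort(seed = 3, n_links = 5)
  dM <- genus_deltas(sim)
  dP <- delta_host(host_parameter_pair(sim$host_t0, sim$host_t29))
  kept <- threshold_edges(pairwise_correlations(dM, dP, min_n = 5), 0.6)
  net <- build_network(kept)
  expect_equal(nrow(net$nodes),
               dplyr::n_distinct(kept$microbial_param) + dplyr::n_distinct(kept$host_param))
  expect_true(all(net$edges$microbial_param %in% net$nodes$id[net$nodes$type == "microbial"]))

  dup <- tibble::tibble(microbial_param = "same_id", host_param = "same_id",
                        tau = 0.9, n_pairs = 8, sign = 1L)
  expect_error(build_network(dup), "non-bipartite")
})

test_that("connected components match a breadth-first-search oracle", {
  chain <- tibble::tibble(microbial_param = c("m1", "m2"), host_param = c("h1", "h1"),
                          tau = c(0.7, 0.8), n_pairs = 10, sign = 1L)
  cc <- connected_components(build_network(chain))
  expect_equal(cc$summary$n_nodes, 3)
  expect_equal(cc$summary$n_edges, 2)

  disjoint <- tibble::tibble(microbial_param = paste0("m", 1:4),
                             host_param = paste0("h", 1:4),
                             tau = 0.9, n_pairs = 10, sign = 1L)
  expect_equal(nrow(connected_components(build_network(disjoint))$summary), 4)

  set.seed(22)
  for (i in 1:10) {
    edges <- tibble::tibble(
      microbial_param = sample(paste0("m", 1:8), 12, TRUE),
      host_param = sample(paste0("h", 1:8), 12, TRUE),
      tau = runif(12, 0.65, 1), n_pairs = 10, sign = 1L)
    edges <- dplyr::distinct(edges, microbial_param, host_param, .keep_all = TRUE)
    cc <- connected_components(build_network(edges))
    oracle <- bfs_components(edges)
    # identical partitions up to component relabeling
    got <- cc$membership$component_id[match(names(oracle), cc$membership$node_id)]
    expect_equal(dplyr::n_distinct(got), dplyr::n_distinct(oracle))
    tab <- table(got, oracle)
    expect_true(all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1))
  }
})

test_that("component report counts phyla and edge signs correctly", {
  info <- tibble::tibble(
    param_id = paste0("g__G", 1:8), kind = "abundance", rank = "genus",
    taxon = paste0("G", 1:8),
    phylum = c(rep("Firmicutes", 5), rep("Bacteroidetes", 2), "Proteobacteria"))
  edges <- tibble::tibble(
    microbial_param = c(paste0("g__G", 1:8), "g__G1", "g__G1"),
    host_param = c(rep("h_carb_ox", 8), "h_fat_ox", "h_rq"),
    tau = c(rep(0.7, 5), -0.7, -0.66, 0.7, -0.7, 0.8), n_pairs = 10,
    sign = c(rep(1L, 5), -1L, -1L, 1L, -1L, 1L))
  net <- build_network(edges, info)
  cc <- connected_components(net)
  rep <- component_report(cc, net)
  expect_equal(nrow(rep), 1)
  pb <- rep$phylum_breakdown[[1]]
  expect_equal(unname(pb["Firmicutes"]), 5)
  expect_equal(sum(pb), 8)
  expect_equal(rep$n_positive, sum(edges$tau >= 0))
  expect_equal(rep$n_negative, sum(edges$tau < 0))
  expect_equal(nrow(component_report(connected_components(build_network(edges[0, ])),
                                     build_network(edges[0, ]))), 0)
})

test_that("injected missing values only shrink n_pairs, never add edges", {
  sim <- tiny_cohort(seed = 8, n_links = 2)
  dM <- genus_deltas(sim)
  dP <- delta_host(host_parameter_pair(sim$host_t0, sim$host_t29))
  co_full <- pairwise_correlations(dM, dP, min_n = 5)
  dP_na <- dP
  dP_na[2:6, 2] <- NA  # 5 of 10 subjects missing for host param 1
  co_na <- pairwise_correlations(dM, dP_na, min_n = 8)
  hurt <- co_na[co_na$host_param == names(dP)[2], ]
  expect_true(all(hurt$n_pairs == 5))
  expect_true(all(is.na(hurt$tau)))
  expect_true(all(co_na$n_pairs <= co_full$n_pairs))
})
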