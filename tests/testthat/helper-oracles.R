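# Independent oracles used to cross-check the implementation.

# O(n^2) pair-enumeration Kendall tau-b with tie corrections.
tau_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  ties <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  (conc - disc) / sqrt((n0 - ties(x)) * (n0 - ties(y)))
}

# Brute-force connected components by breadth-first search on an edge list.
bfs_components <- function(edges) {
  nodes <- unique(c(edges$microbial_param, edges$host_param))
  adj <- lapply(stats::setNames(nodes, nodes), function(n) {
    c(edges$host_param[edges$microbial_param == n],
      edges$microbial_param[edges$host_param == n])
  })
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    k <- k + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

# Small cohort shared across tests.
tiny_cohort <- function(seed = 42, n_links = 3) {
  cfg <- cohort_config(n_subjects = 10, n_genera = 20, n_phyla = 4,
                       host_params_total = 15, n_links = n_links, seed = seed)
  simulate_cohort(cfg)
}

# Deltas straight from generated counts (even libraries: no subsampling).
genus_deltas <- function(sim, depth = NULL, seed = 1) {
  mp <- build_microbiota_parameters(sim$counts_t0, sim$counts_t29, sim$taxonomy,
                                    depth = depth, seed = seed,
                                    ratios = FALSE, indices = FALSE)
  dM <- delta_microbiota(mp)
  dM[c("subject_id", grep("^g__", names(dM), value = TRUE))]
}
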