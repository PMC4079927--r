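# Synthetic paired-cohort generator: paired (t0, t29) microbiota count tables,
# a ranked taxonomy, and host-parameter tables with planted, ground-truth
# associations between microbial and host changes.

#' Configure a synthetic paired intervention cohort
#'
#' Bundles every knob of the synthetic generator into one validated list.
#' Defaults emulate a small human dietary-intervention cohort: strong,
#' persistent between-subject differences in the faecal community, subtle
#' within-subject shifts over the intervention, and multinomial read sampling
#' at a realistic amplicon sequencing depth.
#'
#' @param n_subjects Number of subjects, each sampled at t0 and t29.
#' @param n_genera,n_phyla Size of the generated taxonomy.
#' @param sequencing_depth Reads drawn per sample (multinomial total).
#' @param between_subject_sd SD of per-subject latent log-abundances around the
#'   taxon means; controls persistent inter-individual structure.
#' @param within_subject_shift_sd SD of the per-subject, per-taxon latent
#'   log-abundance shift between t0 and t29. Must stay below
#'   `between_subject_sd` so inter-individual differences dominate the
#'   intervention effect, mirroring the study design this emulates.
#' @param n_links,link_strength Convenience for auto-planted links: `n_links`
#'   microbial-host associations of this strength are planted on the most
#'   abundant genera (alternating sign) unless `planted_links` is given.
#' @param planted_links Optional tibble with columns `microbial_param`
#'   (a genus `taxon_id`), `host_param`, `sign` (+1/-1) and `strength` in
#'   (0, 1]; `strength` is the target Kendall tau magnitude between the latent
#'   microbial change and the host relative change at large n with
#'   `host_noise_sd = 0`.
#' @param host_params_total Number of host parameters.
#' @param host_noise_sd SD of additional noise on host relative changes, on the
#'   same scale as the planted relative-change signal (internal scale 0.1,
#'   i.e. ~10% typical relative changes).
#' @param seed Master seed; all sub-generators derive child seeds from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 10,
                          n_genera = 115,
                          n_phyla = 8,
                          sequencing_depth = 2500,
                          between_subject_sd = 1.0,
                          within_subject_shift_sd = 0.45,
                          n_links = 0,
                          link_strength = 0.9,
                          planted_links = NULL,
                          host_params_total = 96,
                          host_noise_sd = 0.05,
                          seed = 1L) {
  check_positive_int(n_subjects, "n_subjects")
  check_positive_int(n_genera, "n_genera")
  check_positive_int(n_phyla, "n_phyla")
  check_positive_int(sequencing_depth, "sequencing_depth")
  check_positive_real(between_subject_sd, "between_subject_sd")
  check_positive_real(within_subject_shift_sd, "within_subject_shift_sd", strict = FALSE)
  check_positive_real(host_noise_sd, "host_noise_sd", strict = FALSE)
  check_positive_int(host_params_total, "host_params_total")
  if (n_phyla < 2) stop_config("`n_phyla` must be at least 2.")
  if (n_genera < n_phyla) stop_config("`n_genera` must be >= `n_phyla`.")
  if (within_subject_shift_sd >= between_subject_sd) {
    stop_config("`within_subject_shift_sd` must be smaller than `between_subject_sd`: the generator encodes inter-individual differences prevailing over intervention shifts.")
  }
  if (!is.null(planted_links)) planted_links <- validate_planted_links(planted_links)
  if (n_links > host_params_total) stop_config("`n_links` exceeds `host_params_total`.")
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_genera = as.integer(n_genera),
      n_phyla = as.integer(n_phyla), sequencing_depth = as.integer(sequencing_depth),
      between_subject_sd = between_subject_sd,
      within_subject_shift_sd = within_subject_shift_sd,
      n_links = as.integer(n_links), link_strength = link_strength,
      planted_links = planted_links,
      host_params_total = as.integer(host_params_total),
      host_noise_sd = host_noise_sd, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

validate_planted_links <- function(links) {
  links <- tibble::as_tibble(links)
  needed <- c("microbial_param", "host_param", "sign", "strength")
  missing <- setdiff(needed, names(links))
  if (length(missing)) {
    stop_config(paste0("planted_links is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(links$sign %in% c(-1, 1))) stop_config("planted link `sign` must be +1 or -1.")
  if (!all(links$strength > 0 & links$strength <= 1)) {
    stop_config("planted link `strength` must lie in (0, 1].")
  }
  links
}

real_phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Actinobacteria",
                "Verrucomicrobia", "Fusobacteria", "Tenericutes", "Cyanobacteria")

#' Generate a complete five-rank taxonomy
#'
#' Produces a phylum-to-genus taxonomy that always contains the phyla
#' Firmicutes and Bacteroidetes and the genera Bacteroides (family
#' Bacteroidaceae) and Prevotella (family Prevotellaceae), both under
#' Bacteroidetes, so that the community-level ratio parameters
#' (Firmicutes/Bacteroidetes, Prevotella/Bacteroides) are always exercisable.
#' Remaining genera are assigned to phyla with Firmicutes-weighted
#' probabilities, matching the typical dominance structure of the human gut.
#'
#' @param n_phyla Number of phyla (>= 2).
#' @param n_genera Number of genera (>= n_phyla).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A tibble with columns `taxon_id`, `phylum`, `class`, `order`,
#'   `family`, `genus` (one row per genus; `taxon_id == genus`).
#' @export
generate_taxonomy <- function(n_phyla, n_genera, seed = 1L) {
  check_positive_int(n_phyla, "n_phyla")
  check_positive_int(n_genera, "n_genera")
  if (n_phyla < 2) stop_config("`n_phyla` must be at least 2.")
  if (n_genera < n_phyla) stop_config("`n_genera` must be >= `n_phyla`.")

  with_seed_(derive_seed(seed, 11L), {
    phyla <- c(real_phyla[seq_len(min(n_phyla, length(real_phyla)))],
               if (n_phyla > length(real_phyla)) {
                 sprintf("Phylum%02d", seq_len(n_phyla - length(real_phyla)))
               })

    # Per-phylum class/order/family scaffold; Bacteroidetes uses the real
    # lineage so the forced genera sit where they do in nature.
    scaffold <- lapply(phyla, function(ph) {
      if (ph == "Bacteroidetes") {
        tibble::tibble(phylum = ph, class = "Bacteroidia", order = "Bacteroidales",
                       family = c("Bacteroidaceae", "Prevotellaceae", "Porphyromonadaceae"))
      } else {
        n_fam <- sample(1:3, 1)
        tibble::tibble(phylum = ph,
                       class = paste0(ph, "_c1"),
                       order = paste0(ph, "_o1"),
                       family = paste0(ph, "_f", seq_len(n_fam)))
      }
    })
    scaffold <- dplyr::bind_rows(scaffold)

    forced <- tibble::tibble(
      taxon_id = c("Bacteroides", "Prevotella"),
      phylum = "Bacteroidetes", class = "Bacteroidia", order = "Bacteroidales",
      family = c("Bacteroidaceae", "Prevotellaceae"),
      genus = c("Bacteroides", "Prevotella")
    )

    n_free <- n_genera - 2L
    free_names <- if (n_free > 0) sprintf("Genus%03d", seq_len(n_free)) else character()

    # Cover phyla without a genus first (as far as the genus budget allows),
    # then distribute the rest with gut-like weights.
    empty_phyla <- setdiff(phyla, "Bacteroidetes")
    assignment <- character(n_free)
    k <- min(length(empty_phyla), n_free)
    if (k > 0) assignment[seq_len(k)] <- empty_phyla[seq_len(k)]
    if (n_free > k) {
      w <- ifelse(phyla == "Firmicutes", 0.45,
                  ifelse(phyla == "Bacteroidetes", 0.2, 0.35 / max(1, n_phyla - 2)))
      assignment[(k + 1):n_free] <- sample(phyla, n_free - k, replace = TRUE, prob = w)
    }

    free <- purrr::map2_dfr(free_names, assignment, function(g, ph) {
      fam <- scaffold[scaffold$phylum == ph, ]
      row <- fam[sample(nrow(fam), 1), ]
      tibble::tibble(taxon_id = g, phylum = row$phylum, class = row$class,
                     order = row$order, family = row$family, genus = g)
    })

    out <- dplyr::bind_rows(forced, free)
    out[order(out$taxon_id), ]
  })
}

#' Generate paired microbiota count tables
#'
#' Logistic-normal latent model with multinomial read sampling. Each subject
#' draws one latent log-abundance vector (taxon means + between-subject
#' variation) shared by both time points; t29 adds an independent per-taxon
#' shift with SD `within_subject_shift_sd`. Counts are multinomial draws of
#' `sequencing_depth` reads from the softmax of the latent log-abundances.
#' The latent (count-noise-free) change in relative abundance is returned so
#' host parameters can be linked to exact ground truth.
#'
#' @param config A [cohort_config()].
#' @param taxonomy Taxonomy tibble from [generate_taxonomy()]; its genera
#'   define the taxa.
#' @return List with `counts_t0`, `counts_t29` (tibbles, first column
#'   `sample_id`, integer taxon counts), and `latent_delta` (tibble of latent
#'   relative-abundance changes t29 - t0 per subject and taxon).
#' @export
generate_paired_counts <- function(config, taxonomy) {
  stopifnot(inherits(config, "cohort_config"))
  taxa <- sort(taxonomy$taxon_id)
  if (length(taxa) != config$n_genera) {
    stop_config("taxonomy size does not match `n_genera` in the config.")
  }
  S <- config$n_subjects; G <- length(taxa)
  subjects <- sprintf("S%02d", seq_len(S))

  with_seed_(derive_seed(config$seed, 23L), {
    mu <- stats::rnorm(G, 0, 1)                      # taxon-level mean log abundance
    base <- matrix(stats::rnorm(S * G, 0, config$between_subject_sd), S, G)
    base <- sweep(base, 2, mu, `+`)
    shift <- matrix(stats::rnorm(S * G, 0, config$within_subject_shift_sd), S, G)
    lat0 <- base
    lat29 <- base + shift
    p0 <- softmax_rows(lat0)
    p29 <- softmax_rows(lat29)
    draw <- function(p) {
      cnt <- t(apply(p, 1, function(pr) stats::rmultinom(1, config$sequencing_depth, pr)[, 1]))
      dimnames(cnt) <- list(subjects, taxa)
      cnt
    }
    c0 <- draw(p0)
    c29 <- draw(p29)
    dimnames(p0) <- dimnames(p29) <- list(subjects, taxa)
    list(
      counts_t0 = matrix_to_tbl(c0, "sample_id"),
      counts_t29 = matrix_to_tbl(c29, "sample_id"),
      latent_delta = matrix_to_tbl(p29 - p0, "sample_id"),
      latent_p0 = matrix_to_tbl(p0, "sample_id")
    )
  })
}

# Map a target tau magnitude to the latent Pearson correlation that yields it
# for bivariate normal data (Greiner's relation).
tau_to_rho <- function(tau) sin(pi * tau / 2)

#' Generate host-parameter tables with planted associations
#'
#' Baselines are drawn from per-parameter normal distributions with strictly
#' positive means (truncated below at 5% of the mean), so relative changes are
#' always well defined on synthetic data. For each planted link, the host
#' parameter's relative change is built from the standardized latent change of
#' the linked genus so that the expected Kendall tau equals the link's
#' `strength` (sign as planted) at large n with `host_noise_sd = 0`; extra
#' noise attenuates it. Unlinked parameters receive pure-noise relative
#' changes.
#'
#' @param config A [cohort_config()].
#' @param microbial_deltas Latent delta tibble from [generate_paired_counts()]
#'   (`latent_delta`), plus optionally `latent_p0` used to auto-place links on
#'   the most abundant genera when the config gives only `n_links`.
#' @param latent_p0 Baseline latent relative abundances (for auto link
#'   placement); optional when `config$planted_links` is explicit.
#' @return List with `host_t0`, `host_t29` (tibbles, first column
#'   `subject_id`) and `ground_truth` (list with the planted link table and
#'   the config snapshot).
#' @export
generate_host_parameters <- function(config, microbial_deltas, latent_p0 = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  dm <- tbl_to_matrix(microbial_deltas)
  S <- nrow(dm)
  H <- config$host_params_total
  subjects <- rownames(dm)
  host_ids <- sprintf("host_%02d", seq_len(H))

  links <- config$planted_links
  if (is.null(links) && config$n_links > 0) {
    if (is.null(latent_p0)) stop_config("latent_p0 is required to auto-place planted links.")
    mean_share <- colMeans(tbl_to_matrix(latent_p0))
    top <- names(sort(mean_share, decreasing = TRUE))[seq_len(config$n_links)]
    links <- tibble::tibble(
      microbial_param = top,
      host_param = host_ids[seq_len(config$n_links)],
      sign = rep_len(c(1, -1), config$n_links),
      strength = config$link_strength
    )
  }
  if (is.null(links)) {
    links <- tibble::tibble(microbial_param = character(), host_param = character(),
                            sign = numeric(), strength = numeric())
  }
  bad_m <- setdiff(links$microbial_param, colnames(dm))
  if (length(bad_m)) stop_config(paste0("planted link references unknown microbial parameter(s): ",
                                        paste(bad_m, collapse = ", ")))
  bad_h <- setdiff(links$host_param, host_ids)
  if (length(bad_h)) stop_config(paste0("planted link references unknown host parameter(s): ",
                                        paste(bad_h, collapse = ", ")))

  rel_scale <- 0.1  # typical magnitude of relative host changes (~10%)

  with_seed_(derive_seed(config$seed, 37L), {
    means <- stats::runif(H, 20, 200)
    t0 <- sapply(seq_len(H), function(j) {
      pmax(stats::rnorm(S, means[j], 0.15 * means[j]), 0.05 * means[j])
    })
    rel <- matrix(stats::rnorm(S * H, 0, config$host_noise_sd), S, H)
    if (nrow(links)) {
      for (k in seq_len(nrow(links))) {
        j <- match(links$host_param[k], host_ids)
        z <- dm[, links$microbial_param[k]]
        sdz <- stats::sd(z)
        z <- if (sdz > 0) (z - mean(z)) / sdz else z * 0
        rho <- tau_to_rho(links$strength[k])
        sig <- links$sign[k] * (rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(S))
        # linked params: planted signal replaces the baseline pure-noise draw
        rel[, j] <- sig * rel_scale + stats::rnorm(S, 0, config$host_noise_sd)
      }
    }
    t29 <- t0 * (1 + rel)
    dimnames(t0) <- dimnames(t29) <- list(subjects, host_ids)
    list(
      host_t0 = matrix_to_tbl(t0, "subject_id"),
      host_t29 = matrix_to_tbl(t29, "subject_id"),
      ground_truth = structure(list(links = links, config = config),
                               class = "cohort_truth")
    )
  })
}

#' Simulate a full paired cohort
#'
#' Convenience wrapper chaining [generate_taxonomy()],
#' [generate_paired_counts()] and [generate_host_parameters()].
#'
#' @param config A [cohort_config()].
#' @return List with `taxonomy`, `counts_t0`, `counts_t29`, `latent_delta`,
#'   `host_t0`, `host_t29`, `ground_truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  taxonomy <- generate_taxonomy(config$n_phyla, config$n_genera, seed = config$seed)
  counts <- generate_paired_counts(config, taxonomy)
  host <- generate_host_parameters(config, counts$latent_delta, counts$latent_p0)
  c(list(taxonomy = taxonomy),
    counts[c("counts_t0", "counts_t29", "latent_delta", "latent_p0")], host)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("Synthetic cohort ground truth:", nrow(x$links), "planted link(s)\n")
  if (nrow(x$links)) print(x$links)
  invisible(x)
}
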