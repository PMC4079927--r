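# Community metrics: rarefaction, rank aggregation, relative abundance,
# alpha-diversity indices, taxon ratios, Bray-Curtis and UPGMA clustering.

taxonomic_ranks <- c("phylum", "class", "order", "family", "genus")

check_counts_tbl <- function(tbl, arg = "table") {
  m <- tbl_to_matrix(tbl)
  if (any(is.na(m))) rlang::abort(sprintf("`%s` contains missing values.", arg))
  if (any(m < 0)) rlang::abort(sprintf("`%s` contains negative values.", arg))
  m
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (the subsampling normalization used for uneven amplicon libraries).
#' Samples with fewer than `depth` total reads are dropped and reported via
#' the `"dropped"` attribute and a message.
#'
#' @param table Count tibble (first column sample id, integer counts).
#' @param depth Target reads per sample (default 1000).
#' @param seed Integer seed; subsampling is deterministic given the seed.
#' @return Rarefied count tibble with attribute `"dropped"` listing removed
#'   sample ids.
#' @export
rarefy <- function(table, depth = 1000, seed = 1L) {
  if (depth <= 0) rlang::abort("`depth` must be positive.")
  m <- check_counts_tbl(table)
  if (any(m != floor(m))) rlang::abort("rarefy() requires integer counts.")
  totals <- rowSums(m)
  drop <- rownames(m)[totals < depth]
  keep <- m[totals >= depth, , drop = FALSE]
  if (length(drop)) {
    rlang::inform(paste0("rarefy: dropped ", length(drop), " sample(s) below depth ",
                         depth, ": ", paste(drop, collapse = ", ")))
  }
  if (nrow(keep) == 0) rlang::abort("rarefy: no sample reaches the requested depth.")
  # suppress vegan's advisory about singleton counts; inputs are validated above
  sub <- with_seed_(derive_seed(seed, 3L), suppressWarnings(vegan::rrarefy(keep, depth)))
  out <- matrix_to_tbl(sub, names(table)[1])
  attr(out, "dropped") <- drop
  out
}

#' Aggregate taxon columns to a taxonomic rank
#'
#' Sums columns over taxa sharing the named rank; per-sample totals are
#' conserved at every rank. Output columns are ordered lexicographically.
#'
#' @param table Abundance tibble (counts or relative), first column sample id.
#' @param taxonomy Taxonomy tibble ([generate_taxonomy()] layout).
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @return Aggregated tibble.
#' @export
aggregate_by_rank <- function(table, taxonomy, rank) {
  rank <- match.arg(rank, taxonomic_ranks)
  id_name <- names(table)[1]
  taxa <- names(table)[-1]
  unknown <- setdiff(taxa, taxonomy$taxon_id)
  if (length(unknown)) {
    rlang::abort(paste0("taxa absent from taxonomy: ", paste(unknown, collapse = ", ")))
  }
  map <- taxonomy[[rank]][match(taxa, taxonomy$taxon_id)]
  m <- tbl_to_matrix(table)
  agg <- t(rowsum(t(m), group = map))
  agg <- agg[, order(colnames(agg)), drop = FALSE]
  matrix_to_tbl(agg, id_name)
}

#' Convert counts to relative abundances
#'
#' @param table Count tibble; every row sum must be positive.
#' @return Tibble whose rows sum to 1.
#' @export
relative_abundance <- function(table) {
  m <- check_counts_tbl(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    rlang::abort(paste0("all-zero sample(s): ",
                        paste(rownames(m)[totals == 0], collapse = ", ")))
  }
  matrix_to_tbl(m / totals, names(table)[1])
}

#' Shannon diversity index (nats)
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive abundance; higher H
#' means higher diversity.
#'
#' @param p Relative-abundance vector (sums to 1, entries >= 0).
#' @return H in nats.
#' @export
shannon <- function(p) {
  if (any(p < 0)) rlang::abort("negative abundances in `p`.")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Simpson diversity index
#'
#' `D = sum(p_i^2)`: the probability two random reads share a taxon. Larger D
#' means lower diversity (D decreases with increasing diversity).
#'
#' @inheritParams shannon
#' @return D in (0, 1].
#' @export
simpson <- function(p) {
  if (any(p < 0)) rlang::abort("negative abundances in `p`.")
  sum(p^2)
}

#' Observed richness
#'
#' Number of taxa with count > 0 in a sample.
#'
#' @param counts Count vector for one sample.
#' @return Integer richness.
#' @export
richness <- function(counts) {
  if (any(counts < 0)) rlang::abort("negative counts.")
  sum(counts > 0)
}

#' Per-sample diversity indices
#'
#' Computes Shannon (nats), Simpson (sum of squared proportions) and observed
#' richness for every sample of a count table. Typically applied to rarefied
#' counts so depth differences do not masquerade as diversity differences.
#'
#' @param table Count tibble.
#' @return Tibble with columns `sample_id`, `shannon`, `simpson`, `richness`.
#' @export
diversity_indices <- function(table) {
  m <- check_counts_tbl(table)
  totals <- rowSums(m)
  if (any(totals == 0)) rlang::abort("all-zero sample(s); cannot compute diversity.")
  p <- m / totals
  tibble::tibble(
    sample_id = rownames(m),
    shannon = apply(p, 1, shannon),
    simpson = apply(p, 1, simpson),
    richness = apply(m, 1, richness)
  )
}

#' Per-sample abundance ratio between two taxa
#'
#' Ratio parameters such as Firmicutes/Bacteroidetes (phylum level) or
#' Prevotella/Bacteroides (genus level). With `pseudocount = 0` (default) a
#' zero denominator yields `NA` with a warning; a small pseudocount keeps the
#' ratio finite and flags the affected samples.
#'
#' @param table Abundance tibble aggregated at the appropriate rank.
#' @param numerator,denominator Column (taxon) names.
#' @param pseudocount Added to both numerator and denominator (default 0).
#' @return Tibble with `sample_id`, `ratio`, and logical `zero_denominator`.
#' @export
taxon_ratio <- function(table, numerator, denominator, pseudocount = 0) {
  for (tx in c(numerator, denominator)) {
    if (!tx %in% names(table)) rlang::abort(paste0("taxon not in table: ", tx))
  }
  num <- table[[numerator]] + pseudocount
  den <- table[[denominator]] + pseudocount
  zero <- table[[denominator]] == 0
  ratio <- ifelse(den == 0, NA_real_, num / den)
  if (any(zero) && pseudocount == 0) {
    rlang::warn(paste0("taxon_ratio: zero denominator for ", sum(zero),
                       " sample(s); ratio set to NA."))
  }
  tibble::tibble(sample_id = as.character(table[[1]]), ratio = ratio,
                 zero_denominator = zero)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(i, j) = 1 - 2 * sum(min(x_i, x_j)) / (sum(x_i) + sum(x_j))`, between 0 and 1.
#'
#' @param table Abundance tibble (counts or relative); no empty samples.
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  m <- check_counts_tbl(table)
  if (any(rowSums(m) == 0)) rlang::abort("empty sample(s); Bray-Curtis undefined.")
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering producing an ultrametric tree.
#' Leaf ids are sorted lexicographically before clustering so equal-distance
#' merges resolve toward the lexicographically smaller pair.
#'
#' @param dm Symmetric distance matrix with ids as dimnames (>= 2 leaves).
#' @return An [ape::as.phylo()] tree; branch lengths are height differences,
#'   so two leaves at distance d merge at height d/2. The underlying `hclust`
#'   object is attached as attribute `"hclust"`.
#' @export
upgma <- function(dm) {
  if (any(is.na(dm))) rlang::abort("distance matrix contains NaN/NA.")
  if (nrow(dm) < 2) rlang::abort("need at least 2 leaves.")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  tree <- ape::as.phylo(hc)
  attr(tree, "hclust") <- hc
  tree
}

#' Export a dendrogram as a Newick string or file
#'
#' @param tree A `phylo` tree (e.g. from [upgma()]).
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return Newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) ape::write.tree(tree)
  else invisible(ape::write.tree(tree, file = path))
}
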