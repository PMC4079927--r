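make_counts <- function(m, ids = sprintf("S%d", seq_len(nrow(m)))) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("T%d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(m))
}

test_that("rarefaction normalizes depth, keeps whole samples, drops shallow ones", {
  tbl <- make_counts(rbind(c(600, 400, 171), c(900, 80, 19), c(300, 100, 50)))
  rr <- suppressMessages(rarefy(tbl, depth = 1000, seed = 1))
  expect_equal(attr(rr, "dropped"), c("S2", "S3"))
  expect_equal(sum(rr[1, -1]), 1000)

  # a sample holding exactly `depth` reads is returned unchanged
  exact <- make_counts(matrix(c(700, 300), 1))
  expect_equal(rarefy(exact, depth = 1000, seed = 1), exact, ignore_attr = TRUE)

  expect_identical(suppressMessages(rarefy(tbl, 1000, seed = 3)),
                   suppressMessages(rarefy(tbl, 1000, seed = 3)))
  expect_error(rarefy(tbl, depth = 0))
})

test_that("rarefied proportions follow the hypergeometric expectation", {
  tbl <- make_counts(matrix(c(900, 100), 1))
  n_rep <- 2000
  draws <- vapply(seq_len(n_rep), function(s) {
    as.numeric(rarefy(tbl, depth = 100, seed = s)[[2]])
  }, numeric(1))
  se <- sqrt(0.9 * 0.1 * 100 * (1000 - 100) / (1000 - 1)) / sqrt(n_rep)
  expect_lt(abs(mean(draws) - 90), 3 * se)
})

test_that("rank aggregation sums lineages and conserves totals", {
  tx <- tibble::tibble(taxon_id = c("Bacteroides", "Prevotella"),
                       phylum = "Bacteroidetes", class = "Bacteroidia",
                       order = "Bacteroidales",
                       family = c("Bacteroidaceae", "Prevotellaceae"),
                       genus = c("Bacteroides", "Prevotella"))
  tbl <- make_counts(matrix(c(5, 3), 1, dimnames = list(NULL, c("Bacteroides", "Prevotella"))))
  ph <- aggregate_by_rank(tbl, tx, "phylum")
  expect_equal(ph$Bacteroidetes, 8)
  gen <- aggregate_by_rank(tbl, tx, "genus")
  expect_equal(gen[, sort(names(tbl))], tbl[, sort(names(tbl))])

  set.seed(1)
  big_tx <- generate_taxonomy(4, 25, seed = 1)
  m <- matrix(rpois(6 * 25, 20), 6, 25, dimnames = list(NULL, sort(big_tx$taxon_id)))
  big <- make_counts(m)
  for (rk in c("phylum", "class", "order", "family", "genus")) {
    agg <- aggregate_by_rank(big, big_tx, rk)
    expect_equal(rowSums(agg[-1]), rowSums(big[-1]), ignore_attr = TRUE)
  }
  expect_error(aggregate_by_rank(make_counts(matrix(1, 1, 1,
    dimnames = list(NULL, "Nope"))), big_tx, "phylum"), "Nope")
})

test_that("relative abundance divides by row totals and rejects empty samples", {
  tbl <- make_counts(matrix(c(10, 30, 60), 1))
  expect_equal(as.numeric(relative_abundance(tbl)[1, -1]), c(0.1, 0.3, 0.6))
  one <- make_counts(matrix(5, 1, 1))
  expect_equal(as.numeric(relative_abundance(one)[1, -1]), 1)
  set.seed(2)
  r <- make_counts(matrix(rpois(40, 8) + 1, 5, 8))
  expect_equal(rowSums(relative_abundance(r)[-1]), rep(1, 5), ignore_attr = TRUE)
  expect_error(relative_abundance(make_counts(matrix(0, 1, 3))), "all-zero")
})

test_that("diversity indices match closed forms and bounds", {
  expect_equal(shannon(rep(0.25, 4)), log(4))
  expect_equal(shannon(1), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  expect_equal(simpson(rep(1 / 7, 7)), 1 / 7)
  expect_equal(simpson(1), 1)
  expect_equal(simpson(c(0.5, 0.25, 0.25)), 0.375)
  expect_equal(richness(c(5, 0, 1)), 2)
  expect_equal(richness(c(0, 0)), 0)
  expect_error(shannon(c(-0.1, 1.1)))

  # zero-abundance taxon changes nothing; H bounded by log richness
  set.seed(3)
  for (i in 1:20) {
    p <- as.numeric(rmultinom(1, 500, runif(8))) / 500
    expect_equal(shannon(c(p, 0)), shannon(p))
    expect_lte(shannon(p), log(richness(p)) + 1e-12)
    expect_gte(simpson(p), 1 / max(1, richness(p)))
  }
})

test_that("merging two taxa lowers diversity for both indices", {
  set.seed(4)
  for (i in 1:100) {
    k <- sample(3:10, 1)
    p <- as.numeric(rmultinom(1, 1000, runif(k))) / 1000
    p <- p[p > 0]
    if (length(p) < 2) next
    merged <- c(p[1] + p[2], p[-(1:2)])
    expect_lte(shannon(merged), shannon(p) + 1e-12)
    expect_gte(simpson(merged), simpson(p) - 1e-12)
  }
})

test_that("taxon ratios reproduce the dominant-phyla example and flag zeros", {
  tbl <- make_counts(matrix(c(0.77, 0.11), 1,
                            dimnames = list(NULL, c("Firmicutes", "Bacteroidetes"))))
  expect_equal(taxon_ratio(tbl, "Firmicutes", "Bacteroidetes")$ratio, 7)
  eq <- make_counts(matrix(c(4, 4), 1, dimnames = list(NULL, c("A", "B"))))
  expect_equal(taxon_ratio(eq, "A", "B")$ratio, 1)
  z <- make_counts(matrix(c(3, 0), 1, dimnames = list(NULL, c("A", "B"))))
  expect_warning(r0 <- taxon_ratio(z, "A", "B"), "zero denominator")
  expect_true(is.na(r0$ratio) && r0$zero_denominator)
  r1 <- taxon_ratio(z, "A", "B", pseudocount = 1e-6)
  expect_true(is.finite(r1$ratio) && r1$zero_denominator)
})

test_that("Bray-Curtis matches the hand example and its metric properties", {
  tbl <- make_counts(rbind(c(6, 4, 0), c(2, 4, 4)), ids = c("A", "B"))
  bc <- bray_curtis(tbl)
  expect_equal(bc["A", "B"], 0.4)

  set.seed(5)
  r <- make_counts(matrix(rpois(60, 15) + 1, 6, 10))
  d <- bray_curtis(r)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 6), ignore_attr = TRUE)
  expect_true(all(d >= 0 & d <= 1))
  # identical samples -> 0; disjoint supports -> 1
  same <- make_counts(rbind(c(1, 2, 3), c(1, 2, 3)), ids = c("A", "B"))
  expect_equal(bray_curtis(same)["A", "B"], 0)
  disj <- make_counts(rbind(c(5, 0), c(0, 9)), ids = c("A", "B"))
  expect_equal(bray_curtis(disj)["A", "B"], 1)
  # invariant to jointly relabeling taxa
  perm <- sample(10)
  r2 <- dplyr::bind_cols(r[1], r[-1][perm])
  expect_equal(bray_curtis(r2), bray_curtis(r))
})

test_that("UPGMA merges two leaves at half their distance", {
  dm <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(write_newick(upgma(dm)), "(A:0.2,B:0.2);")
})

test_that("UPGMA rebuilds a known ultrametric tree from its cophenetic matrix", {
  set.seed(6)
  x <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(LETTERS[1:8], NULL))
  hc <- stats::hclust(dist(x), method = "average")
  coph <- as.matrix(stats::cophenetic(hc))
  rebuilt <- upgma(coph)
  expect_equal(as.matrix(stats::cophenetic(attr(rebuilt, "hclust"))),
               coph[rownames(coph)[order(rownames(coph))],
                    colnames(coph)[order(colnames(coph))]],
               tolerance = 1e-10)
  # output is ultrametric: all three-point conditions hold
  cm <- as.matrix(stats::cophenetic(attr(rebuilt, "hclust")))
  n <- nrow(cm)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    trio <- sort(c(cm[i, j], cm[i, k], cm[j, k]), decreasing = TRUE)
    expect_lte(trio[1], trio[2] + 1e-10)
  }
})

test_that("UPGMA topology is invariant to leaf order and rejects NaN", {
  set.seed(7)
  x <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(paste0("L", 1:6), NULL))
  dm <- as.matrix(dist(x))
  t1 <- upgma(dm)
  perm <- sample(6)
  t2 <- upgma(dm[perm, perm])
  expect_equal(as.matrix(stats::cophenetic(attr(t1, "hclust"))),
               as.matrix(stats::cophenetic(attr(t2, "hclust")))[rownames(dm)[order(rownames(dm))],
                                                                rownames(dm)[order(rownames(dm))]])
  dm[1, 2] <- dm[2, 1] <- NaN
  expect_error(upgma(dm), "NaN")
})
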