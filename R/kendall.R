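# Kendall tau-b and its small-n null distribution.

#' Kendall tau-b between two vectors
#'
#' Tie-corrected Kendall rank correlation on pairwise-complete observations:
#' `tau_b = (C - D) / sqrt((n0 - n1) * (n0 - n2))` with `n0 = n(n-1)/2` and
#' `n1`, `n2` the tied-pair counts of each vector. Constant input (after
#' pairwise deletion) or fewer than `min_n` complete pairs yields an `NA` tau
#' with the reason recorded.
#'
#' @param x,y Numeric vectors of equal length; `NA`s allowed.
#' @param min_n Minimum complete pairs required (default 2).
#' @return List with `tau`, `n_pairs`, and `reason` (`NA` when defined).
#' @export
kendall_tau <- function(x, y, min_n = 2L) {
  if (length(x) != length(y)) rlang::abort("`x` and `y` must have equal length.")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < max(2L, min_n)) {
    return(list(tau = NA_real_, n_pairs = n, reason = "too_few_pairs"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(tau = NA_real_, n_pairs = n, reason = "constant_input"))
  }
  tau <- stats::cor(x, y, method = "kendall")
  list(tau = tau, n_pairs = n, reason = NA_character_)
}

# All permutations of 1..n as an (n! x n) matrix, in lexicographic-ish
# recursive order. Used only for n <= 8 (40320 rows).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep.int(k, rows), ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

# Tau (no ties) of each row-permutation against the identity ranking,
# via concordance counts over all i < j pairs.
perm_tau <- function(perms) {
  n <- ncol(perms)
  pairs <- utils::combn(n, 2)
  n0 <- n * (n - 1) / 2
  conc <- rowSums(sapply(seq_len(ncol(pairs)), function(k) {
    sign(perms[, pairs[2, k]] - perms[, pairs[1, k]])
  }))
  conc / n0
}

#' Null distribution of |tau| at small n
#'
#' Probability that `|tau| >= cutoff` under the null of a uniformly random
#' ranking (no ties), by full permutation enumeration for `n <= 8` and by
#' Monte-Carlo permutation sampling (with standard error) for larger n.
#' Useful for judging the per-pair false-edge rate implied by a raw-tau
#' threshold at the small cohort sizes typical of intervention studies
#' (e.g. n = 10).
#'
#' @param n Number of paired observations (>= 3).
#' @param cutoff Threshold on |tau| in (0, 1].
#' @param n_mc Monte-Carlo permutations when enumeration is infeasible
#'   (default 1e5).
#' @param seed Seed for the Monte-Carlo path.
#' @return List with `probability`, `se` (0 for enumeration), `method`,
#'   and `n_used` (number of permutations evaluated).
#' @export
exact_tau_null <- function(n, cutoff, n_mc = 1e5, seed = 1L) {
  if (n < 3) rlang::abort("`n` must be at least 3.")
  if (cutoff <= 0 || cutoff > 1) rlang::abort("`cutoff` must lie in (0, 1].")
  eps <- 1e-12
  if (n <= 8) {
    taus <- perm_tau(all_permutations(as.integer(n)))
    p <- mean(abs(taus) >= cutoff - eps)
    list(probability = p, se = 0, method = "enumeration", n_used = length(taus))
  } else {
    with_seed_(derive_seed(seed, 7L), {
      perms <- t(replicate(n_mc, sample.int(n)))
      taus <- perm_tau(perms)
      p <- mean(abs(taus) >= cutoff - eps)
      list(probability = p, se = sqrt(p * (1 - p) / n_mc),
           method = "monte_carlo", n_used = n_mc)
    })
  }
}
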