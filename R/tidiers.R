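# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PLS model
#'
#' One row per predictor with the original-scale coefficient and, when the
#' model carries jackknife diagnostics, the jackknife SE, t-like statistic
#' and selection flag.
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pls_model <- function(x, ...) {
  if (!is.null(x$jackknife)) return(x$jackknife)
  cf <- x$coefficients[-1]
  tibble::tibble(variable = names(cf), coefficient = unname(cf))
}

#' One-line summary of a PLS model
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `n_predictors`, `n_components`,
#'   `r_squared`, `q_squared` (when cross-validated) and `n_selected`.
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(
    n = length(x$y),
    n_predictors = length(x$x_means),
    n_components = x$n_components,
    r_squared = x$r_squared,
    q_squared = if (!is.null(x$cv)) x$cv$q2$q2[x$cv$n_components] else NA_real_,
    n_selected = if (!is.null(x$jackknife)) sum(x$jackknife$selected) else NA_integer_
  )
}

#' Tidy a bipartite network (its edge list)
#'
#' @param x A `bipartite_network`.
#' @param ... Unused.
#' @return Edge tibble with tau, sign and pair counts.
#' @export
tidy.bipartite_network <- function(x, ...) x$edges

#' One-line summary of a bipartite network
#'
#' @param x A `bipartite_network`.
#' @param ... Unused.
#' @return One-row tibble of node/edge/component counts.
#' @export
glance.bipartite_network <- function(x, ...) {
  comps <- connected_components(x)
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_microbial = sum(x$nodes$type == "microbial"),
    n_host = sum(x$nodes$type == "host"),
    n_edges = nrow(x$edges),
    n_positive = sum(x$edges$tau >= 0),
    n_negative = sum(x$edges$tau < 0),
    n_components = nrow(comps$summary)
  )
}
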