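# ggplot2 visualizations of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_col
#'   geom_boxplot labs theme_minimal scale_color_manual coord_flip
#' @export
ggplot2::autoplot

#' Plot a bipartite correlation network
#'
#' Force-directed layout (deterministic given `seed`); node shape/color by
#' type, edge color by correlation sign, edge width by |tau|.
#'
#' @param object A `bipartite_network`.
#' @param seed Layout seed.
#' @param label Label nodes with their parameter ids (default TRUE for
#'   networks up to 60 nodes).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bipartite_network <- function(object, seed = 1L,
                                       label = nrow(object$nodes) <= 60, ...) {
  if (nrow(object$edges) == 0) {
    return(ggplot() + labs(title = "Empty network") + theme_minimal())
  }
  g <- network_igraph(object)
  xy <- with_seed_(derive_seed(seed, 77L), igraph::layout_with_fr(g))
  nodes <- object$nodes
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  edges <- object$edges
  edges$x <- nodes$x[match(edges$microbial_param, nodes$id)]
  edges$y <- nodes$y[match(edges$microbial_param, nodes$id)]
  edges$xend <- nodes$x[match(edges$host_param, nodes$id)]
  edges$yend <- nodes$y[match(edges$host_param, nodes$id)]
  edges$sign <- ifelse(edges$tau >= 0, "positive", "negative")
  p <- ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                     color = .data$sign, linewidth = abs(.data$tau)), alpha = 0.7) +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, shape = .data$type, fill = .data$type),
               size = 3, color = "grey20") +
    ggplot2::scale_shape_manual(values = c(microbial = 21, host = 24)) +
    ggplot2::scale_fill_manual(values = c(microbial = "#39a055", host = "grey10")) +
    scale_color_manual(values = c(positive = "#c23b22", negative = "#3b6fc2")) +
    ggplot2::scale_linewidth(range = c(0.3, 1.4), guide = "none") +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   axis.title = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank()) +
    labs(color = "correlation", shape = "parameter", fill = "parameter")
  if (label) {
    p <- p + ggplot2::geom_text(data = nodes,
                                aes(x = .data$x, y = .data$y, label = .data$id),
                                size = 2.6, vjust = -1)
  }
  p
}

#' Plot PLS coefficients with jackknife selection
#'
#' @param object A `pls_model` (ideally from [pls_analysis()]).
#' @param top Show at most this many variables by |coefficient| (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pls_model <- function(object, top = 25, ...) {
  tab <- tidy(object)
  if (!"selected" %in% names(tab)) tab$selected <- TRUE
  tab <- tab[order(-abs(tab$coefficient)), ][seq_len(min(top, nrow(tab))), ]
  tab$variable <- factor(tab$variable, levels = rev(tab$variable))
  ggplot(tab, aes(x = .data$variable, y = .data$coefficient, fill = .data$selected)) +
    geom_col() +
    coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#39a055", `FALSE` = "grey70")) +
    theme_minimal() +
    labs(x = NULL, y = "PLS coefficient (original scale)",
         fill = "jackknife-selected")
}

#' Compare diversity indices between time points
#'
#' Boxplots of Shannon, Simpson and richness for samples labelled by time
#' point (ids ending in `_t0` / `_t29`, as produced by [run_pipeline()]).
#'
#' @param diversity Tibble from [diversity_indices()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(diversity) {
  d <- diversity
  d$time_point <- ifelse(grepl("_t29$", d$sample_id), "t29",
                         ifelse(grepl("_t0$", d$sample_id), "t0", "all"))
  long <- tidyr::pivot_longer(d, c("shannon", "simpson", "richness"),
                              names_to = "index", values_to = "value")
  ggplot(long, aes(x = .data$time_point, y = .data$value)) +
    geom_boxplot(outlier.shape = NA) +
    geom_point(position = ggplot2::position_jitter(width = 0.1, seed = 1),
               alpha = 0.6, size = 1.5) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    theme_minimal() +
    labs(x = NULL, y = NULL)
}
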