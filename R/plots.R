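#' Volcano-style plot of a differential flux table
#'
#' Plots each tested reaction's group contrast (difference of group mean
#' fluxes) against `-log10(p)`, coloring significant reactions by
#' direction.
#'
#' @param object A `flux_diff_tbl` from [differential_flux()].
#' @param label_top Number of most significant reactions to label.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flux_diff_tbl
#' @export
autoplot.flux_diff_tbl <- function(object, label_top = 5, ...) {
  df <- dplyr::filter(as_tibble(object), .data$tested)
  df$delta <- df$mean_lesion - df$mean_control
  df$state <- ifelse(!df$significant, "not significant", df$direction)
  top <- utils::head(df[order(df$p), ], label_top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                   y = -log10(pmax(.data$p, 1e-16)),
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$reaction),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(
      "up" = "#b2182b", "down" = "#2166ac", "not significant" = "grey60")) +
    ggplot2::labs(x = "flux difference (lesion - control)",
                  y = expression(-log[10] * "(p)"),
                  colour = NULL, title = "Differential flux") +
    ggplot2::theme_minimal()
}

#' Consensus matrix heatmap
#'
#' Tile heatmap of the consensus matrix at a given k, with genes ordered
#' by the hierarchical consensus clustering.
#'
#' @param object A `consensus_result` from [consensus_cluster()].
#' @param k Which k's matrix to draw (default the chosen k).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, k = object$chosen_k, ...) {
  M <- object$consensus[[as.character(k)]]
  ord <- hclust(as.dist(1 - M), method = "average")$order
  M <- M[ord, ord]
  df <- tibble(
    row = factor(rep(rownames(M), times = ncol(M)), levels = rownames(M)),
    col = factor(rep(colnames(M), each = nrow(M)), levels = colnames(M)),
    consensus = as.vector(M)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus matrix (k = %d)", k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot a gene network
#'
#' Simple force-directed layout of a [consensus_network()] or
#' [ppi_ingest()] result.
#'
#' @param net A `gene_network`.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_gene_network <- function(net, seed = 1L) {
  g <- as_igraph(net)
  xy <- with_local_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(node = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  edges <- dplyr::left_join(net$edges, nodes, by = c("from" = "node")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes, by = c("to" = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y,
                                       linewidth = .data$weight),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 3, colour = "#2166ac") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$node),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
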