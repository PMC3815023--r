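#' Plot the DPG-vs-background similarity distributions
#'
#' Empirical CDFs of the defined similarity scores per namespace, DPG pairs
#' against the random-pair background; the plot version of the KS
#' comparison.
#'
#' @param object A `dpg_sim_compare` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dpg_sim_compare <- function(object, ...) {
  dat <- bind_rows(
    mutate(object$dpg_scores, set = "DPG pairs"),
    mutate(object$background_scores, set = "random pairs"))
  dat <- dat[!is.na(dat$score), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, colour = .data$set)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::facet_wrap(~namespace) +
    ggplot2::labs(x = "GO similarity (Schlicker relevance, rcmax.avg)",
                  y = "empirical CDF", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a set network
#'
#' Nodes are functional sets (sized by membership), edges the retained map
#' edges (width by rate); modules, when given, colour their member nodes.
#'
#' @param object A `dpg_set_network` object.
#' @param modules Optional `dpg_modules` object.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dpg_set_network <- function(object, modules = NULL, seed = 1, ...) {
  g <- as_igraph(object)
  lay <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(set_name = igraph::V(g)$name,
                  size = igraph::V(g)$size,
                  x = lay[, 1], y = lay[, 2])
  nodes$module <- "none"
  if (!is.null(modules) && nrow(modules) > 0L) {
    for (i in seq_len(nrow(modules))) {
      nodes$module[nodes$set_name %in% modules$members[[i]]] <-
        sprintf("module %d", modules$module[i])
    }
  }
  ed <- object$edges |>
    left_join(nodes[, c("set_name", "x", "y")], by = c(set_a = "set_name")) |>
    left_join(nodes[, c("set_name", "x", "y")], by = c(set_b = "set_name"),
              suffix = c("", "_b"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_b, yend = .data$y_b,
                                       linewidth = .data$weight),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$size,
                                     colour = .data$module)) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, size = "set size",
                  linewidth = paste(object$map_kind, "rate"))
}

#' Plot pathway perturbation levels
#'
#' Absolute and relative perturbation levels per functional set, as a
#' two-row tile strip.
#'
#' @param scores Score tibble from [score_pathways()].
#' @return A ggplot object.
#' @export
plot_score_levels <- function(scores) {
  dat <- tidyr::pivot_longer(
    scores[, c("set_name", "absolute_level", "relative_level")],
    -"set_name", names_to = "kind", values_to = "level")
  dat$kind <- sub("_level", "", dat$kind)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$set_name, y = .data$kind,
                                    fill = factor(.data$level, levels = 0:5))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_brewer(palette = "YlOrRd", drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "perturbation level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
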