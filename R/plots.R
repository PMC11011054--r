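#' Plot block counts across the hierarchy
#'
#' One line per node type showing how many blocks (clusters for cells,
#' topics for genes) each hierarchy level contains.
#'
#' @param object An [fit_sbm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sbm_fit
#' @export
autoplot.sbm_fit <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(x = .data$level, y = .data$n_blocks,
                               colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "hierarchy level (0 = finest)", y = "number of blocks",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of centered topic probabilities per cluster
#'
#' The centered probability `Pc(topic | cluster)` for every cluster-topic
#' pair, with the adaptively assigned pairs outlined — the heatmap view of
#' a topic-to-cluster assignment.
#'
#' @param object An [assign_topics_to_clusters()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_topic_assignment
#' @export
autoplot.cluster_topic_assignment <- function(object, ...) {
  dat <- object$pc_cluster |>
    dplyr::mutate(assigned = paste(.data$cluster, .data$topic) %in%
                    paste(object$assignment$cluster, object$assignment$topic))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$cluster),
                                    y = factor(.data$topic),
                                    fill = .data$pc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(dat, .data$assigned),
                       fill = NA, colour = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "cluster", y = "topic",
                  fill = "Pc(topic | cluster)",
                  caption = sprintf("final n = %.2f", object$n)) +
    ggplot2::theme_minimal()
}

#' Cluster composition against known labels
#'
#' Stacked bar chart of how cells with known labels (e.g. tumor of origin)
#' distribute over the clusters of one hierarchy level.
#'
#' @param fit An [fit_sbm()] result.
#' @param labels Tibble with `cell` and `group` columns.
#' @param level Hierarchy level (default 0).
#' @return A ggplot object.
#' @export
plot_cluster_composition <- function(fit, labels, level = 0) {
  stopifnot(all(c("cell", "group") %in% names(labels)))
  dat <- cell_clusters(fit, level) |>
    dplyr::inner_join(labels, by = "cell") |>
    dplyr::count(.data$cluster, .data$group)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$cluster), y = .data$n,
                                    fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("cluster (level %d)", level), y = "cells",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
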