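#' Gene-to-topic probability table
#'
#' For a hard block partition each gene belongs to exactly one topic; its
#' probability within the topic is degree-based:
#' `P(gene | topic) = k_gene / e_topic`, where `k_gene` is the total edge
#' multiplicity incident to the gene and `e_topic` the total multiplicity
#' incident to all genes of the topic. Probabilities of genes outside the
#' topic are zero and are omitted from the long table.
#'
#' @param fit An [fit_sbm()] result.
#' @param level Hierarchy level (0 = finest).
#' @param layer Layer name; defaults to the first layer.
#' @return A tibble with `gene`, `topic`, `prob`; `prob` sums to 1 within
#'   each topic.
#' @export
gene_topic_distribution <- function(fit, level = 0, layer = NULL) {
  stopifnot(inherits(fit, "sbm_fit"))
  if (is.null(layer)) layer <- fit$graph$layers[1]
  gt <- gene_topics(fit, level, layer)
  idx <- graph_layer_genes(fit$graph, layer)
  deg <- fit$graph$nodes$degree[idx]
  gt |>
    dplyr::mutate(k = deg) |>
    dplyr::group_by(.data$topic) |>
    dplyr::mutate(prob = .data$k / sum(.data$k)) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "topic", "prob") |>
    dplyr::arrange(.data$topic, dplyr::desc(.data$prob))
}

#' Topic-to-cell probability table
#'
#' `P(topic | cell) = e(cell, topic) / k_cell`, where `e(cell, topic)` is
#' the edge multiplicity between the cell and the topic's genes and
#' `k_cell` the cell's degree restricted to the topic's layer, so that each
#' cell's probabilities over one layer's topics sum to 1. In multipartite
#' fits each layer is normalized within itself.
#'
#' Cells with zero degree in the layer get all-zero rows; their identifiers
#' are attached as the `zero_degree_cells` attribute.
#'
#' @inheritParams gene_topic_distribution
#' @return A tibble with `cell`, `topic`, `prob` (zero entries omitted
#'   except for zero-degree cells, which appear once with `prob = 0` and
#'   `topic = NA`).
#' @export
topic_cell_distribution <- function(fit, level = 0, layer = NULL) {
  stopifnot(inherits(fit, "sbm_fit"))
  if (is.null(layer)) layer <- fit$graph$layers[1]
  graph <- fit$graph
  lev <- as.character(level)
  gidx <- graph_layer_genes(graph, layer)
  if (length(gidx) == 0) stop("no genes for layer '", layer, "'", call. = FALSE)
  topic_of_node <- rep(NA_integer_, nrow(graph$nodes))
  topic_of_node[gidx] <- as.integer(factor(fit$memberships[gidx, lev]))
  cells <- graph$nodes$node[graph_cells(graph)]

  e <- graph$edges
  in_layer <- !is.na(topic_of_node[e$to])
  tab <- tibble::tibble(
    cell = graph$nodes$node[e$from[in_layer]],
    topic = topic_of_node[e$to[in_layer]],
    weight = e$weight[in_layer]
  ) |>
    dplyr::group_by(.data$cell, .data$topic) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop_last") |>
    dplyr::mutate(prob = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup() |>
    dplyr::select("cell", "topic", "prob")

  zero_cells <- setdiff(cells, unique(tab$cell))
  if (length(zero_cells) > 0)
    tab <- dplyr::bind_rows(
      tab, tibble::tibble(cell = zero_cells, topic = NA_integer_, prob = 0))
  tab <- dplyr::arrange(tab, match(.data$cell, cells), .data$topic)
  attr(tab, "zero_degree_cells") <- zero_cells
  attr(tab, "layer") <- layer
  tab
}

#' All probability tables of a fitted model at one level
#'
#' Convenience wrapper returning the cell clustering and, per layer, the
#' gene-topic and topic-cell tables.
#'
#' @inheritParams gene_topic_distribution
#' @return A list with `clusters` ([cell_clusters()] tibble) and per-layer
#'   `gene_topic` / `topic_cell` tibbles (named by layer).
#' @export
topic_model_result <- function(fit, level = 0) {
  stopifnot(inherits(fit, "sbm_fit"))
  layers <- fit$graph$layers
  list(
    level = level,
    clusters = cell_clusters(fit, level),
    gene_topic = stats::setNames(
      lapply(layers, function(l) gene_topic_distribution(fit, level, l)), layers),
    topic_cell = stats::setNames(
      lapply(layers, function(l) topic_cell_distribution(fit, level, l)), layers)
  )
}
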