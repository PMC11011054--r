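#' Build the weighted gene-cell multigraph
#'
#' Translates one or more count layers into the weighted multipartite graph
#' the block model is fitted to. Nodes are cells plus one gene node per gene
#' and layer; a gene is connected to a cell by a multiedge whose integer
#' multiplicity is the (discretized) count. Genes never connect to genes and
#' cells never connect to cells, so with one layer the graph is bipartite
#' and with two layers it is tripartite with the cells shared between
#' layers and no edge between the two gene layers.
#'
#' Entries that discretize to zero produce no edge; genes or cells left with
#' zero degree are removed from the graph (dropped cells are recorded in the
#' `dropped_cells` field so downstream cluster tables stay aligned).
#'
#' @param layers A [count_layer()] or list of count layers sharing an
#'   identical cell list. Layer names must be distinct.
#' @param weight_mode How to discretize counts into edge multiplicities:
#'   `"raw-integer"` (default) requires the counts to already be integers
#'   and uses them as-is; `"round"` rounds (half-to-even); `"floor"` takes
#'   the integer part.
#'
#' @return An object of class `cell_gene_graph`: a list with a `nodes`
#'   tibble (`node`, `type`, `degree`), an `edges` tibble (`from`, `to`,
#'   `weight`, 1-based node indices), the total edge multiplicity `E`, the
#'   layer names, and `dropped_cells`.
#' @export
build_graph <- function(layers, weight_mode = c("raw-integer", "round", "floor")) {
  weight_mode <- match.arg(weight_mode)
  if (inherits(layers, "count_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1, all(vapply(layers, inherits, TRUE, "count_layer")))
  layer_names <- vapply(layers, function(l) l$layer_name, character(1))
  if (anyDuplicated(layer_names))
    stop("layer names must be distinct", call. = FALSE)
  cells <- layers[[1]]$cells
  for (l in layers[-1])
    if (!identical(l$cells, cells))
      stop("all layers must share an identical cell list", call. = FALSE)

  triplets <- purrr::map2(layers, seq_along(layers), function(l, i) {
    m <- methods::as(l$counts, "TsparseMatrix")
    if (any(!is.finite(m@x))) stop("counts must be finite", call. = FALSE)
    w <- switch(weight_mode,
      "raw-integer" = {
        if (any(m@x != round(m@x)))
          stop("weight_mode 'raw-integer' requires integer counts; ",
               "use 'round' or 'floor' for normalized values", call. = FALSE)
        as.integer(m@x)
      },
      "round" = as.integer(round(m@x)),
      "floor" = as.integer(floor(m@x))
    )
    keep <- w > 0
    tibble::tibble(
      gene = paste0(l$genes, "@", l$layer_name)[m@i + 1L][keep],
      cell = cells[m@j + 1L][keep],
      layer = i,
      weight = w[keep]
    )
  }) |> purrr::list_rbind()

  if (nrow(triplets) == 0)
    stop("graph is empty after discretization", call. = FALSE)

  used_cells <- cells[cells %in% unique(triplets$cell)]
  dropped_cells <- setdiff(cells, used_cells)
  gene_nodes <- tibble::tibble(
    node = unique(triplets$gene),
    type = paste0("gene@", layer_names[triplets$layer[!duplicated(triplets$gene)]])
  )
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = used_cells, type = "cell"),
    gene_nodes
  )
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$node)
  edges <- tibble::tibble(
    from = unname(idx[triplets$cell]),
    to = unname(idx[triplets$gene]),
    weight = triplets$weight
  )
  degree <- numeric(nrow(nodes))
  dsum <- tapply(c(edges$weight, edges$weight), c(edges$from, edges$to), sum)
  degree[as.integer(names(dsum))] <- as.numeric(dsum)
  nodes$degree <- degree

  structure(
    list(nodes = nodes, edges = edges, E = sum(edges$weight),
         layers = layer_names, dropped_cells = dropped_cells),
    class = "cell_gene_graph"
  )
}

#' @export
print.cell_gene_graph <- function(x, ...) {
  tab <- table(x$nodes$type)
  cat(sprintf("<cell_gene_graph: %s; %d distinct edges, total multiplicity %d>\n",
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(x$edges), as.integer(x$E)))
  if (length(x$dropped_cells))
    cat(" dropped cells (zero degree):", length(x$dropped_cells), "\n")
  invisible(x)
}

# integer type codes for the C++ core: cell = 0, gene layers in layer order
graph_type_codes <- function(graph) {
  lev <- c("cell", paste0("gene@", graph$layers))
  match(graph$nodes$type, lev) - 1L
}

# node indices (1-based) of cells / of genes in a given layer
graph_cells <- function(graph) which(graph$nodes$type == "cell")
graph_layer_genes <- function(graph, layer) {
  which(graph$nodes$type == paste0("gene@", layer))
}
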