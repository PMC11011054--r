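#' Write pipeline outputs to a directory
#'
#' Writes the probability tables and cluster map of a
#' [topic_model_result()] as TSV files
#' (`L{level}_gene_topic_{layer}.tsv`, `L{level}_topic_cell_{layer}.tsv`,
#' `L{level}_clusters.tsv`), the optional topic-to-cluster assignment
#' (`L{level}_assignment.tsv`), and a `run_metadata.json` record.
#'
#' @param result A [topic_model_result()].
#' @param out_dir Output directory; created (recursively) if missing.
#' @param assignment Optional [assign_topics_to_clusters()] result.
#' @param run_info Named list merged into the metadata record (e.g. seed,
#'   n_init, levels).
#' @return Invisibly, a character vector manifest of the files written.
#' @export
write_results <- function(result, out_dir, assignment = NULL,
                          run_info = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  lv <- result$level
  manifest <- character(0)
  wr <- function(tab, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(tab, path, progress = FALSE)
    manifest <<- c(manifest, path)
  }
  for (layer in names(result$gene_topic))
    wr(result$gene_topic[[layer]],
       sprintf("L%d_gene_topic_%s.tsv", lv, layer))
  for (layer in names(result$topic_cell))
    wr(result$topic_cell[[layer]],
       sprintf("L%d_topic_cell_%s.tsv", lv, layer))
  wr(result$clusters, sprintf("L%d_clusters.tsv", lv))
  if (!is.null(assignment)) {
    wr(tidy(assignment), sprintf("L%d_assignment.tsv", lv))
    run_info$assignment_n <- assignment$n
  }
  meta <- c(list(level = lv,
                 n_clusters = length(unique(result$clusters$cluster)),
                 layers = names(result$gene_topic),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            run_info)
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  manifest <- c(manifest, meta_path)
  invisible(manifest)
}

#' End-to-end topic-model pipeline
#'
#' Normalizes each raw layer, selects highly variable genes, subsets the
#' raw counts to those genes, builds the (bi- or tripartite) gene-cell
#' graph and fits the hierarchical block model.
#'
#' @param layers A [count_layer()] or list of raw count layers sharing
#'   cells.
#' @param target_sum Library-size normalization target (default 1e4).
#' @param min_disp Highly-variable threshold, recycled per layer (default
#'   0.5); the layers may need distinct thresholds when their intrinsic
#'   coefficients of variation differ.
#' @param n_bins Mean bins for dispersion normalization (default 20).
#' @param weight_mode Passed to [build_graph()] (default "raw-integer":
#'   edge multiplicities are the raw counts of the selected genes).
#' @param ... Passed to [fit_sbm()] (`n_init`, `seed`, ...).
#' @return A list with `fit` (an `sbm_fit`), `graph`, and `hvg_layers`
#'   (the selected raw-count layers).
#' @export
run_topic_model <- function(layers, target_sum = 1e4, min_disp = 0.5,
                            n_bins = 20, weight_mode = "raw-integer", ...) {
  if (inherits(layers, "count_layer")) layers <- list(layers)
  min_disp <- rep_len(min_disp, length(layers))
  hvg_layers <- purrr::map2(layers, seq_along(layers), function(l, i) {
    norm <- normalize_library_size(l, target_sum = target_sum)
    hv <- select_highly_variable(norm, min_disp = min_disp[i], n_bins = n_bins)
    # subset the *raw* counts to the selected genes and surviving cells
    count_layer(l$counts[match(hv$genes, l$genes),
                         match(hv$cells, l$cells), drop = FALSE],
                genes = hv$genes, cells = hv$cells,
                layer_name = l$layer_name)
  })
  graph <- build_graph(hvg_layers, weight_mode = weight_mode)
  fit <- fit_sbm(graph, ...)
  list(fit = fit, graph = graph, hvg_layers = hvg_layers)
}

#' Level with a cluster count closest to a target
#'
#' Deterministic rule for picking the "level-appropriate" cell partition
#' when comparing against a known grouping: the hierarchy level whose
#' number of cell clusters is closest to the target number of groups, with
#' ties resolved towards the finer level.
#'
#' @param fit An [fit_sbm()] result.
#' @param n_groups Target number of groups.
#' @return The level (integer, 0 = finest).
#' @export
closest_level <- function(fit, n_groups) {
  stopifnot(inherits(fit, "sbm_fit"))
  counts <- fit$levels |>
    dplyr::filter(.data$type == "cell") |>
    dplyr::arrange(.data$level)
  best <- which.min(abs(counts$n_blocks - n_groups))
  counts$level[best]
}
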