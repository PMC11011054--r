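#' Filter out overly large gene sets
#'
#' Gene-set databases contain huge catch-all sets that dominate
#' hypergeometric enrichment without carrying specific biology. This filter
#' removes every set whose size exceeds `max_ratio` of the total number of
#' distinct genes in its collection (strictly greater; a set exactly at the
#' ratio is kept). The default 0.15 approximates a pairwise Jaccard
#' redundancy filter at a tiny fraction of its cost, because within a
#' collection set length and redundancy are strongly linked.
#'
#' @param collection A [gene_set_collection()].
#' @param max_ratio Maximal allowed `|set| / total_genes` (default 0.15).
#' @return The filtered collection (`total_genes` is kept at the original
#'   collection's union size, since the ratio is defined against the
#'   collection, not its filtered remainder).
#' @export
filter_gene_sets <- function(collection, max_ratio = 0.15) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0) stop("empty collection", call. = FALSE)
  ratios <- lengths(collection$sets) / collection$total_genes
  keep <- !(ratios > max_ratio)
  if (!any(keep)) {
    warning("all gene sets filtered out at max_ratio = ", max_ratio,
            call. = FALSE)
    out <- collection
    out$sets <- collection$sets[0]
    return(out)
  }
  out <- collection
  out$sets <- collection$sets[keep]
  out
}

#' Hypergeometric enrichment of a gene list against a collection
#'
#' For each gene set, tests whether the overlap with `topic_genes` is
#' larger than expected when drawing `|topic_genes|` genes at random from
#' the universe: with `N = |universe|`, `K = |set in universe|`,
#' `n = |topic in universe|` and `k` the observed overlap, the p-value is
#' the hypergeometric upper tail `P(X >= k)`.
#'
#' The universe defaults to the intersection-relevant convention used
#' throughout this package: supply the analyzed feature list (e.g. the
#' highly variable genes of the relevant layer) intersected with the
#' collection's gene union.
#'
#' @param topic_genes Character vector of genes to test (a topic's gene
#'   content).
#' @param collection A [gene_set_collection()] (typically pre-filtered with
#'   [filter_gene_sets()]).
#' @param universe Character vector of background genes. Must be non-empty
#'   after deduplication; genes outside it are ignored everywhere.
#' @return A tibble with `set`, `set_size`, `overlap`, `topic_size`,
#'   `universe_size` and `p_value`, sorted by `p_value`.
#' @export
hypergeometric_enrich <- function(topic_genes, collection, universe) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  topic <- intersect(unique(topic_genes), universe)
  N <- length(universe)
  n <- length(topic)
  purrr::imap(collection$sets, function(genes, name) {
    K <- length(intersect(genes, universe))
    k <- length(intersect(genes, topic))
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set = name, set_size = K, overlap = k,
                   topic_size = n, universe_size = N, p_value = p)
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$p_value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction:
#' `q_(i) = min_(j >= i) min(1, p_(j) * m / j)` over the sorted p-values.
#' Thin wrapper over [stats::p.adjust()] with input validation.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return The adjusted q-values, in the input order; always
#'   `q >= p` and `q <= 1`.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Enrich every topic of a fitted model
#'
#' Runs [hypergeometric_enrich()] for each topic's gene content against a
#' collection and BH-adjusts the p-values jointly across all tests of the
#' collection.
#'
#' @param topics A tibble mapping `gene` to `topic` (e.g. from
#'   [gene_topics()]), or a named list of character vectors.
#' @param collection A [gene_set_collection()].
#' @param universe Background genes; defaults to the intersection of the
#'   analyzed genes (those in `topics`) with the collection's gene union.
#' @return A tibble with `topic`, `set`, `overlap`, `p_value`, `q_value`.
#' @export
enrich_topics <- function(topics, collection, universe = NULL) {
  if (is.data.frame(topics)) {
    stopifnot(all(c("gene", "topic") %in% names(topics)))
    topics <- split(topics$gene, topics$topic)
  }
  all_genes <- unique(unlist(topics, use.names = FALSE))
  if (is.null(universe))
    universe <- intersect(all_genes,
                          unique(unlist(collection$sets, use.names = FALSE)))
  res <- purrr::imap(topics, function(genes, id) {
    hypergeometric_enrich(genes, collection, universe) |>
      dplyr::mutate(topic = id, .before = 1)
  }) |> purrr::list_rbind()
  res$q_value <- bh_adjust(res$p_value)
  dplyr::select(res, "topic", "set", "set_size", "overlap", "p_value",
                "q_value")
}

#' Summarize topics by their most enriched gene set
#'
#' Labels each topic with its most enriched (minimum q-value) gene set.
#' When one set is the best label for several topics, only the topic with
#' the smallest q-value keeps it; the others fall back to their next-best
#' set. Ties are broken by larger overlap, then by set name. Topics with
#' no set below `fdr_threshold` are labeled `NA` (unannotated). Run it on
#' the topics actually assigned to cell partitions (see
#' [assign_topics()]), not on every block of the model.
#'
#' @param results An [enrich_topics()] tibble (`topic`, `set`, `overlap`,
#'   `q_value`).
#' @param fdr_threshold Maximal q-value for an annotation (default 0.05).
#' @return A tibble `topic`, `set`, `q_value` with one row per topic.
#' @export
summarize_topic_annotations <- function(results, fdr_threshold = 0.05) {
  stopifnot(all(c("topic", "set", "q_value") %in% names(results)))
  if (!"overlap" %in% names(results)) results$overlap <- 0
  topics <- unique(results$topic)
  cand <- results |>
    dplyr::filter(.data$q_value <= fdr_threshold) |>
    dplyr::arrange(.data$q_value, dplyr::desc(.data$overlap), .data$set)
  label <- stats::setNames(rep(NA_character_, length(topics)), topics)
  qval <- stats::setNames(rep(NA_real_, length(topics)), topics)
  taken <- character(0)
  # greedy in q order: the globally best available (topic, set) pair wins,
  # which implements the "lowest FDR keeps the set" dedup rule
  for (i in seq_len(nrow(cand))) {
    tp <- as.character(cand$topic[i]); st <- cand$set[i]
    if (!is.na(label[tp]) || st %in% taken) next
    label[tp] <- st
    qval[tp] <- cand$q_value[i]
    taken <- c(taken, st)
  }
  tibble::tibble(topic = topics, set = unname(label[as.character(topics)]),
                 q_value = unname(qval[as.character(topics)]))
}
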