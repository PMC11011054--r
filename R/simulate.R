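#' Specification for a synthetic two-layer single-cell experiment
#'
#' Describes planted hierarchical structure mimicking a paired-subtype,
#' sensitive/resistant tumor design: four cell groups (2 subtypes x
#' sensitive/resistant), two count layers sharing the cells, with the
#' second layer noisier (higher per-gene coefficient of variation) and the
#' two layers carrying complementary signal. The defaults plant the
#' subtype split strongly in both layers, but each layer resolves the
#' sensitive/resistant split within only one subtype (layer 1 within the
#' second subtype, layer 2 within the first) — so neither layer alone
#' resolves all four groups, but together they do.
#'
#' Rows of the affinity matrices are groups, columns topics; each cell's
#' topic weights are its group's (normalized) affinity row, each topic
#' owns an exclusive slice of the layer's genes with Dirichlet-distributed
#' within-topic gene probabilities, and counts are multinomial draws of a
#' uniformly drawn sequencing depth. Layer 2 adds per-cell, per-gene gamma
#' rate multipliers with `shape = 1 / dispersion`, giving overdispersed
#' (negative-binomial-like) counts.
#'
#' @param n_cells_per_group Cells per group (default 50; at least 2).
#' @param n_genes Genes per layer, length 2 (default c(200, 150)).
#' @param n_topics Topics per layer, length 2 (default c(4, 4)).
#' @param affinity_1,affinity_2 Group x topic non-negative affinity
#'   matrices; defaults implement the complementary design above.
#' @param dispersion Per-layer gamma dispersion, length 2 (default
#'   c(0.05, 0.6); layer 2 must be noisier for the design to make sense
#'   but this is not enforced).
#' @param depth_range_1,depth_range_2 Sequencing depth ranges (uniform
#'   integer draw) per layer.
#' @param group_names Labels for the four groups.
#' @return A `synthetic_spec` list, to be passed to [simulate_layers()].
#' @export
synthetic_spec <- function(n_cells_per_group = 50,
                           n_genes = c(200, 150),
                           n_topics = c(4, 4),
                           affinity_1 = NULL,
                           affinity_2 = NULL,
                           dispersion = c(0.05, 0.6),
                           depth_range_1 = c(1000, 2000),
                           depth_range_2 = c(300, 800),
                           group_names = c("LumS", "LumR", "TnbS", "TnbR")) {
  n_groups <- length(group_names)
  if (is.null(affinity_1)) {
    # topics: subtype-1 program, subtype-2 program, subtype-2 resistance, shared
    affinity_1 <- rbind(
      LumS = c(6.0, 0.3, 0.3, 3.0),
      LumR = c(6.0, 0.3, 0.3, 3.0),
      TnbS = c(0.3, 6.0, 0.3, 3.0),
      TnbR = c(0.3, 6.0, 2.0, 3.0))
  }
  if (is.null(affinity_2)) {
    # topics: subtype-1 resistance, subtype-1 program, subtype-2 program, shared
    affinity_2 <- rbind(
      LumS = c(0.3, 5.0, 0.3, 3.0),
      LumR = c(3.0, 5.0, 0.3, 3.0),
      TnbS = c(0.3, 0.3, 5.0, 3.0),
      TnbR = c(0.3, 0.3, 5.0, 3.0))
  }
  spec <- list(n_cells_per_group = n_cells_per_group, n_genes = n_genes,
               n_topics = n_topics,
               affinity = list(affinity_1, affinity_2),
               dispersion = dispersion,
               depth_range = list(depth_range_1, depth_range_2),
               group_names = group_names)
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  stopifnot(spec$n_cells_per_group >= 2,
            length(spec$n_genes) == 2, length(spec$n_topics) == 2,
            all(spec$dispersion >= 0),
            all(vapply(spec$depth_range, function(d) all(d > 0), TRUE)))
  for (l in 1:2) {
    if (spec$n_topics[l] > spec$n_genes[l])
      stop("layer ", l, ": more topics than genes", call. = FALSE)
    A <- spec$affinity[[l]]
    if (nrow(A) != length(spec$group_names) || ncol(A) != spec$n_topics[l])
      stop("layer ", l, ": affinity matrix must be groups x topics",
           call. = FALSE)
    if (any(A < 0) || any(rowSums(A) == 0))
      stop("affinities must be non-negative with positive row sums",
           call. = FALSE)
  }
  invisible(spec)
}

#' Generate synthetic two-layer count data with planted structure
#'
#' Draws the experiment described by a [synthetic_spec()]: both layers
#' share the same cells, and the returned truth records each cell's group
#' and each gene's planted topic per layer.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; identical seeds give identical data.
#' @return A list with `layer1`, `layer2` ([count_layer()]s named
#'   `"mRNA"`, `"lncRNA"`), `cell_groups` (tibble `cell`, `group`) and
#'   `gene_topics` (tibble `gene`, `layer`, `topic`).
#' @export
simulate_layers <- function(spec = synthetic_spec(), seed = 1L) {
  validate_synthetic_spec(spec)
  local_seed(seed, {
    n_groups <- length(spec$group_names)
    n_cells <- n_groups * spec$n_cells_per_group
    cells <- sprintf("cell%03d", seq_len(n_cells))
    groups <- rep(spec$group_names, each = spec$n_cells_per_group)
    layer_names <- c("mRNA", "lncRNA")
    layers <- vector("list", 2)
    gene_truth <- vector("list", 2)
    for (l in 1:2) {
      ng <- spec$n_genes[l]
      nt <- spec$n_topics[l]
      genes <- sprintf("%s_g%03d", layer_names[l], seq_len(ng))
      # exclusive topic slices, as equal as possible
      topic_of_gene <- sort(rep_len(seq_len(nt), ng))
      # within-topic gene distributions (Dirichlet(2): even-ish, not flat)
      gene_prob <- numeric(ng)
      for (t in seq_len(nt)) {
        idx <- which(topic_of_gene == t)
        w <- stats::rgamma(length(idx), shape = 2, rate = 1)
        gene_prob[idx] <- w / sum(w)
      }
      A <- spec$affinity[[l]]
      counts <- matrix(0L, nrow = ng, ncol = n_cells)
      depths <- sample(spec$depth_range[[l]][1]:spec$depth_range[[l]][2],
                       n_cells, replace = TRUE)
      disp <- spec$dispersion[l]
      for (c_i in seq_len(n_cells)) {
        wt <- A[match(groups[c_i], spec$group_names), ]
        wt <- wt / sum(wt)
        rate <- gene_prob * wt[topic_of_gene]
        if (disp > 0) {
          rate <- rate * stats::rgamma(ng, shape = 1 / disp, scale = disp)
          if (sum(rate) == 0) rate <- gene_prob * wt[topic_of_gene]
        }
        counts[, c_i] <- stats::rmultinom(1, depths[c_i], rate)
      }
      layers[[l]] <- count_layer(counts, genes = genes, cells = cells,
                                 layer_name = layer_names[l])
      gene_truth[[l]] <- tibble::tibble(gene = genes, layer = layer_names[l],
                                        topic = topic_of_gene)
    }
    list(layer1 = layers[[1]], layer2 = layers[[2]],
         cell_groups = tibble::tibble(cell = cells, group = groups),
         gene_topics = purrr::list_rbind(gene_truth))
  })
}

#' A planted bipartite benchmark graph
#'
#' Single-layer planted-partition benchmark: `n_blocks` cell groups and
#' the same number of gene topics with matched diagonal structure — genes
#' of topic `t` are expressed `signal` times more in cells of group `t`
#' than elsewhere. Useful for testing whether the fit recovers a known
#' partition.
#'
#' @param n_cells,n_genes Total cells and genes.
#' @param n_blocks Number of planted groups/topics (default 4).
#' @param signal Within-block expression rate relative to background
#'   (default 10).
#' @param depth_range Per-cell sequencing depth range (default
#'   c(250, 400)).
#' @param seed Integer seed.
#' @return A list with `layer` (a [count_layer()]), `cell_groups` and
#'   `gene_topics` truth tibbles.
#' @export
simulate_planted_bipartite <- function(n_cells = 200, n_genes = 100,
                                       n_blocks = 4, signal = 10,
                                       depth_range = c(250, 400), seed = 1L) {
  local_seed(seed, {
    cells <- sprintf("cell%03d", seq_len(n_cells))
    genes <- sprintf("g%03d", seq_len(n_genes))
    cell_group <- sort(rep_len(seq_len(n_blocks), n_cells))
    gene_topic <- sort(rep_len(seq_len(n_blocks), n_genes))
    depths <- sample(depth_range[1]:depth_range[2], n_cells, replace = TRUE)
    counts <- matrix(0L, nrow = n_genes, ncol = n_cells)
    for (c_i in seq_len(n_cells)) {
      rate <- ifelse(gene_topic == cell_group[c_i], signal, 1)
      counts[, c_i] <- stats::rmultinom(1, depths[c_i], rate / sum(rate))
    }
    list(layer = count_layer(counts, genes = genes, cells = cells,
                             layer_name = "planted"),
         cell_groups = tibble::tibble(cell = cells, group = cell_group),
         gene_topics = tibble::tibble(gene = genes, topic = gene_topic))
  })
}
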