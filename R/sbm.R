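#' @useDynLib sctopics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

# run code with a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic stream of sub-seeds below 2^31, derived from a master seed
derive_seed <- function(master, k) {
  (as.double(master) %% 65536) * 32749 + 7919 * (k %% 65536) + k %/% 65536
}

#' Create a block-model state
#'
#' A state couples a [build_graph()] graph with a typed partition of its
#' nodes into blocks and maintains the description length incrementally as
#' nodes move. Blocks are type-homogeneous: genes of different layers and
#' cells never share a block. Most users go straight to [fit_sbm()]; the
#' state-level interface exists for diagnostics and for experimenting with
#' the sampler.
#'
#' @param graph A `cell_gene_graph` from [build_graph()].
#' @param partition Integer vector (one entry per node, labels start at 1)
#'   assigning each node to a block. Defaults to all nodes of each type in
#'   one block.
#' @param epsilon Positive smoothing constant of the proposal kernel
#'   (default 1).
#' @param seed Integer seed for the state's internal random stream.
#'
#' @return An object of class `sbm_state`.
#' @export
sbm_state <- function(graph, partition = NULL, epsilon = 1, seed = 1L) {
  stopifnot(inherits(graph, "cell_gene_graph"), epsilon > 0)
  types <- graph_type_codes(graph)
  if (is.null(partition)) partition <- types + 1L
  stopifnot(length(partition) == nrow(graph$nodes))
  ptr <- cpp_state_create(types, graph$edges$from, graph$edges$to,
                          as.integer(graph$edges$weight),
                          as.integer(partition), epsilon, as.double(seed))
  structure(list(ptr = ptr, graph = graph, epsilon = epsilon),
            class = "sbm_state")
}

#' @export
print.sbm_state <- function(x, ...) {
  nb <- cpp_state_n_blocks(x$ptr)
  cat(sprintf("<sbm_state: Sigma = %.4f nats; blocks per type: %s>\n",
              cpp_state_dl(x$ptr), paste(nb, collapse = ", ")))
  invisible(x)
}

#' Description length of a typed partition
#'
#' The description length Sigma (in nats) is the negative log of the
#' degree-corrected microcanonical block-model likelihood times its
#' nonparametric prior, the quantity the MCMC minimizes. Smaller is better.
#'
#' @inheritParams sbm_state
#' @param state Alternatively, an existing `sbm_state`.
#' @return Sigma in nats (finite for any valid state).
#' @export
description_length <- function(graph = NULL, partition = NULL, epsilon = 1,
                               state = NULL) {
  if (is.null(state)) state <- sbm_state(graph, partition, epsilon)
  cpp_state_recompute_dl(state$ptr)
}

#' Current partition of a state
#'
#' @param state An `sbm_state`.
#' @return A tibble with `node`, `type` and `block` (dense labels from 1).
#' @export
state_partition <- function(state) {
  tibble::tibble(node = state$graph$nodes$node,
                 type = state$graph$nodes$type,
                 block = as.integer(cpp_state_partition(state$ptr)))
}

#' Propose a move for one node
#'
#' Samples the block of a random neighbour edge of the node (or uses the
#' supplied block `t`) and draws a target block from the kernel
#' `Pr(s | t) = (e_ts + epsilon) / (e_t + epsilon * B)`, where `e_ts` counts
#' edges between block `t` and candidate `s`, `e_t` the edges between `t`
#' and nodes of the moving node's type, and `B` the number of candidates
#' (the existing same-type blocks plus one fresh block, reported as block
#' 0). With no connections between the blocks the kernel is uniform.
#'
#' @param state An `sbm_state`.
#' @param node Node index (1-based, in `state$graph$nodes` order) or name.
#' @param t Optional conditioning block (internal id); sampled if `NULL`.
#' @return A list with `block` (target; 0 means a fresh block), `t` (the
#'   conditioning block) and `prob` (the kernel probability of the draw).
#' @export
propose_move <- function(state, node, t = NULL) {
  if (is.character(node)) node <- match(node, state$graph$nodes$node)
  cpp_propose(state$ptr, as.integer(node), if (is.null(t)) -1L else as.integer(t))
}

#' Kernel probabilities over all candidate blocks
#'
#' @inheritParams propose_move
#' @param t Conditioning block (internal id).
#' @return A tibble with `block` (0 = fresh block) and `prob`; the
#'   probabilities sum to 1.
#' @export
proposal_probabilities <- function(state, node, t) {
  if (is.character(node)) node <- match(node, state$graph$nodes$node)
  res <- cpp_proposal_probs(state$ptr, as.integer(node), as.integer(t))
  tibble::tibble(block = res$block, prob = res$prob)
}

#' Run MCMC sweeps on a state
#'
#' One sweep proposes one move per node in random order; proposals are
#' drawn from the neighbour-block kernel and accepted by
#' Metropolis-Hastings on the description-length change with the
#' forward/reverse proposal-probability correction. `mode = "greedy"`
#' accepts only strictly improving moves; `mode = "accept-all"` accepts
#' every proposal (an infinite-temperature diagnostic that still respects
#' the typed-block constraint).
#'
#' @param state An `sbm_state` (modified in place).
#' @param n_sweeps Number of sweeps.
#' @param beta Inverse temperature for `mode = "mh"` (default 1).
#' @param mode `"mh"`, `"greedy"` or `"accept-all"`.
#' @return The number of accepted moves, invisibly; the state is updated.
#' @export
mcmc_sweep <- function(state, n_sweeps = 1, beta = 1,
                       mode = c("mh", "greedy", "accept-all")) {
  mode <- match.arg(mode)
  acc <- switch(mode,
    "mh" = cpp_sweep(state$ptr, n_sweeps, beta, 0L, TRUE),
    "greedy" = cpp_sweep(state$ptr, n_sweeps, 0, 1L, TRUE),
    "accept-all" = cpp_sweep(state$ptr, n_sweeps, 0, 0L, TRUE)
  )
  invisible(acc)
}

random_typed_partition <- function(types, b0 = NULL) {
  # assign each node of each type uniformly to one of b0[type] blocks,
  # with globally distinct labels; empty blocks are dropped by compaction
  part <- integer(length(types))
  offset <- 0L
  for (t in sort(unique(types))) {
    idx <- which(types == t)
    bt <- if (is.null(b0)) max(1L, min(length(idx), ceiling(sqrt(length(idx)))))
          else min(b0, length(idx))
    part[idx] <- offset + sample.int(bt, length(idx), replace = TRUE)
    offset <- offset + bt
  }
  # compact labels to 1..B
  as.integer(factor(part))
}

fit_one_init <- function(graph, init_partition, epsilon, seed, beta, tol,
                         patience, max_sweeps, greedy_cap) {
  state <- sbm_state(graph, init_partition, epsilon = epsilon, seed = seed)
  res <- cpp_optimize(state$ptr, beta, tol, patience, max_sweeps, greedy_cap)
  list(state = state, sigma = res$sigma,
       partition = as.integer(cpp_state_partition(state$ptr)))
}

#' Fit the hierarchical multipartite block model
#'
#' Runs `n_init` independent initializations of the MCMC (each: a random
#' typed partition, Metropolis-Hastings sweeps until the description length
#' stops improving, then greedy descent and greedy block merges), keeps the
#' initialization with the smallest description length, and builds the
#' hierarchy above it by recursively fitting the block-level multigraph
#' until a single block per type remains. The number of blocks at every
#' level is inferred, not prescribed.
#'
#' Level 0 is the finest partition; higher levels are coarsenings of the
#' levels below. Cell blocks are *clusters*, gene blocks are *topics*.
#'
#' @param graph A `cell_gene_graph` from [build_graph()].
#' @param n_init Number of independent initializations (default 7).
#' @param epsilon Proposal-kernel smoothing constant (default 1).
#' @param seed Master seed; per-initialization seeds are derived from it,
#'   and identical seeds give identical fits.
#' @param beta Inverse temperature of the MH phase (default 1).
#' @param tol Minimal description-length improvement (nats) that counts as
#'   progress (default 1e-6).
#' @param patience Stop the MH phase after this many sweeps without
#'   progress (default 10).
#' @param max_sweeps Hard cap on MH sweeps per level (default 1000).
#' @param greedy_cap Cap on greedy descent sweeps (default 100).
#' @param b_init Optional initial number of blocks per type; default is
#'   about the square root of the number of nodes of the type, varied
#'   across initializations.
#'
#' @return An object of class `sbm_fit` with fields `graph`, `memberships`
#'   (node x level integer matrix of dense block labels, level 0 first),
#'   `sigma` (the minimum over initializations), `init_sigmas`, `levels`
#'   (per-level, per-type block counts) and `config`.
#' @export
fit_sbm <- function(graph, n_init = 7, epsilon = 1, seed = 1L, beta = 1,
                    tol = 1e-6, patience = 10, max_sweeps = 1000,
                    greedy_cap = 100, b_init = NULL) {
  stopifnot(inherits(graph, "cell_gene_graph"), n_init >= 1)
  types <- graph_type_codes(graph)
  type_sizes <- table(types)
  if (all(type_sizes == 1))
    warning("graph has a single node per type; returning the degenerate ",
            "single-block hierarchy", call. = FALSE)

  # ---- level 0: best of n_init on the full graph ----
  inits <- vector("list", n_init)
  for (i in seq_len(n_init)) {
    s_i <- derive_seed(seed, i)
    init_part <- local_seed(s_i, {
      bi <- if (is.null(b_init)) NULL else b_init
      # vary the initial block count across initializations
      if (is.null(bi) && i > 1 && stats::runif(1) < 0.5)
        random_typed_partition(types, b0 = sample(1:8, 1))
      else random_typed_partition(types, b0 = bi)
    })
    inits[[i]] <- fit_one_init(graph, init_part, epsilon, s_i, beta, tol,
                               patience, max_sweeps, greedy_cap)
  }
  init_sigmas <- vapply(inits, function(x) x$sigma, numeric(1))
  best <- inits[[which.min(init_sigmas)]]
  state <- best$state

  # ---- agglomerative hierarchy on block-level multigraphs ----
  memberships <- list(best$partition)
  repeat {
    nb <- cpp_state_n_blocks(state$ptr)
    if (all(nb <= 1)) break
    bg <- cpp_block_graph(state$ptr)
    block_types <- bg$node_type
    upper <- fit_block_level(block_types, bg$from, bg$to, bg$weight,
                             epsilon, derive_seed(seed, 100 + length(memberships)),
                             n_init, beta, tol, patience, max_sweeps, greedy_cap)
    # compose to original nodes
    prev <- memberships[[length(memberships)]]
    memberships[[length(memberships) + 1]] <- upper$partition[prev]
    state <- upper$state
  }
  memberships <- do.call(cbind, memberships)
  colnames(memberships) <- as.character(seq_len(ncol(memberships)) - 1)

  levels_tbl <- purrr::map(seq_len(ncol(memberships)), function(l) {
    tibble::tibble(level = l - 1L,
                   type = sort(unique(graph$nodes$type))) |>
      dplyr::mutate(n_blocks = vapply(.data$type, function(tp) {
        length(unique(memberships[graph$nodes$type == tp, l]))
      }, numeric(1)))
  }) |> purrr::list_rbind()

  structure(
    list(graph = graph, memberships = memberships, sigma = min(init_sigmas),
         init_sigmas = init_sigmas, levels = levels_tbl,
         config = list(n_init = n_init, epsilon = epsilon, seed = seed,
                       beta = beta, tol = tol, patience = patience,
                       max_sweeps = max_sweeps)),
    class = "sbm_fit"
  )
}

# fit one hierarchy step: partition the block-level multigraph
fit_block_level <- function(block_types, from, to, weight, epsilon, seed,
                            n_init, beta, tol, patience, max_sweeps,
                            greedy_cap) {
  n <- length(block_types)
  make_state <- function(part, s) {
    ptr <- cpp_state_create(as.integer(block_types), as.integer(from),
                            as.integer(to), as.integer(weight),
                            as.integer(part), epsilon, as.double(s))
    list(ptr = ptr)
  }
  best_sigma <- Inf; best_state <- NULL
  for (i in seq_len(n_init)) {
    s_i <- derive_seed(seed, i)
    part <- if (i == 1) seq_len(n) else
      local_seed(s_i, random_typed_partition(as.integer(block_types)))
    st <- make_state(part, s_i)
    res <- cpp_optimize(st$ptr, beta, tol, patience, max_sweeps, greedy_cap)
    if (res$sigma < best_sigma) { best_sigma <- res$sigma; best_state <- st }
  }
  # guarantee progress: if no type was coarsened, force the single merge
  # with the smallest description-length increase
  part <- as.integer(cpp_state_partition(best_state$ptr))
  if (length(unique(part)) == n && n > length(unique(block_types))) {
    bm <- cpp_best_merge(best_state$ptr, -1L)
    if (bm$r1 > 0) {
      cpp_apply_merge(best_state$ptr, bm$r1, bm$r2)
      part <- as.integer(cpp_state_partition(best_state$ptr))
    }
  }
  list(partition = part, state = best_state, sigma = cpp_state_dl(best_state$ptr))
}

#' @export
print.sbm_fit <- function(x, ...) {
  cat(sprintf("<sbm_fit: Sigma = %.2f nats over %d initializations; %d levels>\n",
              x$sigma, length(x$init_sigmas), ncol(x$memberships)))
  print(tidyr::pivot_wider(x$levels, names_from = "type",
                           values_from = "n_blocks"))
  invisible(x)
}

#' @method tidy sbm_fit
#' @export
tidy.sbm_fit <- function(x, ...) {
  m <- x$memberships
  tibble::tibble(
    node = rep(x$graph$nodes$node, ncol(m)),
    type = rep(x$graph$nodes$type, ncol(m)),
    level = rep(as.integer(colnames(m)), each = nrow(m)),
    block = as.integer(m)
  )
}

#' @method glance sbm_fit
#' @export
glance.sbm_fit <- function(x, ...) {
  tibble::tibble(
    sigma = x$sigma,
    n_levels = ncol(x$memberships),
    n_init = x$config$n_init,
    n_nodes = nrow(x$memberships),
    E = x$graph$E,
    best_init = which.min(x$init_sigmas)
  )
}

#' Hard cell-to-cluster assignment at one level
#'
#' @param fit An [fit_sbm()] result.
#' @param level Hierarchy level (0 = finest).
#' @return A tibble with `cell` and `cluster` (dense integer labels).
#' @export
cell_clusters <- function(fit, level = 0) {
  stopifnot(inherits(fit, "sbm_fit"))
  lev <- as.character(level)
  if (!lev %in% colnames(fit$memberships))
    stop("level ", level, " not present in the fit", call. = FALSE)
  cells <- graph_cells(fit$graph)
  raw <- fit$memberships[cells, lev]
  tibble::tibble(cell = fit$graph$nodes$node[cells],
                 cluster = as.integer(factor(raw)))
}

#' Gene-to-topic assignment at one level
#'
#' @inheritParams cell_clusters
#' @param layer Layer name (defaults to the first layer).
#' @return A tibble with `gene` (bare identifier) and `topic`.
#' @export
gene_topics <- function(fit, level = 0, layer = NULL) {
  stopifnot(inherits(fit, "sbm_fit"))
  if (is.null(layer)) layer <- fit$graph$layers[1]
  lev <- as.character(level)
  idx <- graph_layer_genes(fit$graph, layer)
  if (length(idx) == 0) stop("no genes for layer '", layer, "'", call. = FALSE)
  raw <- fit$memberships[idx, lev]
  tibble::tibble(
    gene = sub(paste0("@", layer, "$"), "", fit$graph$nodes$node[idx]),
    topic = as.integer(factor(raw))
  )
}
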