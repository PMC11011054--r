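# a mid-sized planted graph reused across the state-level tests
make_test_state <- function(n_cells = 30, n_genes = 20, seed = 2,
                            state_seed = 7) {
  sim <- simulate_planted_bipartite(n_cells = n_cells, n_genes = n_genes,
                                    n_blocks = 3, seed = seed)
  g <- build_graph(sim$layer)
  types <- sctopics:::graph_type_codes(g)
  part <- withr::with_seed(seed, sctopics:::random_typed_partition(types))
  list(graph = g, state = sbm_state(g, part, seed = state_seed),
       types = types)
}

test_that("the description length is finite and exactly recomputable", {
  # 1-edge graph, single block per type
  g1 <- build_graph(count_layer(matrix(1, 1, 1), genes = "g", cells = "c"))
  st <- sbm_state(g1)
  expect_true(is.finite(description_length(state = st)))

  ts <- make_test_state()
  expect_equal(sctopics:::cpp_state_dl(ts$state$ptr),
               sctopics:::cpp_state_recompute_dl(ts$state$ptr),
               tolerance = 1e-12)
})

test_that("incrementally maintained Sigma tracks a full recompute through 1000 moves", {
  ts <- make_test_state(n_cells = 30, n_genes = 20)
  st <- ts$state
  withr::local_seed(99)
  for (i in 1:1000) {
    v <- sample(length(ts$types), 1)
    cands <- sctopics:::cpp_blocks_of_type(st$ptr, ts$types[v])
    s <- sample(c(cands, 0L), 1)
    sctopics:::cpp_apply_move(st$ptr, v, s)
  }
  expect_equal(sctopics:::cpp_state_dl(st$ptr),
               sctopics:::cpp_state_recompute_dl(st$ptr), tolerance = 1e-9)
})

test_that("merge deltas agree with recomputation from scratch", {
  ts <- make_test_state()
  st <- ts$state
  before <- sctopics:::cpp_state_recompute_dl(st$ptr)
  for (type in 0:1) {
    cands <- sctopics:::cpp_blocks_of_type(st$ptr, type)
    if (length(cands) < 2) next
    d <- sctopics:::cpp_merge_delta(st$ptr, cands[1], cands[2])
    sctopics:::cpp_apply_merge(st$ptr, cands[1], cands[2])
    after <- sctopics:::cpp_state_recompute_dl(st$ptr)
    expect_equal(after - before, d, tolerance = 1e-9)
    before <- after
  }
})

test_that("the proposal kernel reproduces the edge-count ratio formula", {
  # direct substitution: e_ts = 4, e_t = 10, eps = 1, 3 candidates -> 5/13
  # construct a graph where gene block t has 10 edges, 4 into cell block s
  counts <- rbind(g1 = c(4, 3, 3))
  layer <- count_layer(counts, genes = "g1", cells = c("c1", "c2", "c3"))
  g <- build_graph(layer)
  # cells in 2 blocks: {c1} and {c2, c3}; the single gene in its own block
  part <- integer(nrow(g$nodes))
  part[match(c("c1", "c2", "c3", "g1@layer"), g$nodes$node)] <- c(1L, 2L, 2L, 3L)
  st <- sbm_state(g, part, epsilon = 1)
  v <- which(st$graph$nodes$node == "c1")
  gene_internal <- sctopics:::cpp_blocks_of_type(st$ptr, 1L)[1]
  probs <- proposal_probabilities(st, v, gene_internal)
  expect_equal(sum(probs$prob), 1, tolerance = 1e-12)
  # candidates: block of {c1} (e_ts = 4), block of {c2,c3} (e_ts = 6), fresh
  expect_setequal(round(probs$prob, 10),
                  round(c(5 / 13, 7 / 13, 1 / 13), 10))
  expect_equal(probs$prob[probs$block == 0], 1 / 13, tolerance = 1e-12)
})

test_that("a conditioning block with no edges to the moving type is uniform", {
  # tripartite: the block of cell c2 has lncRNA edges only, so conditioning
  # an mRNA-gene move on it leaves every candidate at eps / (eps * B)
  l1 <- count_layer(matrix(c(3, 0), 1), genes = "m1", cells = c("c1", "c2"),
                    layer_name = "mRNA")
  l2 <- count_layer(matrix(c(2, 2), 1), genes = "l1", cells = c("c1", "c2"),
                    layer_name = "lncRNA")
  g <- build_graph(list(l1, l2))
  part <- integer(4)
  part[match(c("c1", "c2", "m1@mRNA", "l1@lncRNA"), g$nodes$node)] <- 1:4
  st <- sbm_state(g, part)
  v <- which(g$nodes$node == "m1@mRNA")
  pm <- state_partition(st)
  t_c2 <- pm$block[pm$node == "c2"]
  probs <- proposal_probabilities(st, v, t_c2)
  expect_equal(probs$prob, rep(1 / nrow(probs), nrow(probs)),
               tolerance = 1e-12)
  expect_equal(sum(probs$prob), 1, tolerance = 1e-12)
})

test_that("empirical proposal frequencies follow the kernel", {
  ts <- make_test_state(n_cells = 12, n_genes = 8)
  st <- ts$state
  v <- which(ts$types == 0)[1]
  t0 <- sctopics:::cpp_blocks_of_type(st$ptr, 1L)[1]
  probs <- proposal_probabilities(st, v, t0)
  n_draw <- 20000
  draws <- vapply(seq_len(n_draw), function(i) propose_move(st, v, t0)$block,
                  numeric(1))
  emp <- as.numeric(table(factor(draws, levels = probs$block))) / n_draw
  se <- sqrt(probs$prob * (1 - probs$prob) / n_draw)
  expect_true(all(abs(emp - probs$prob) <= 3 * se + 1e-12))
})

test_that("accept-all sweeps preserve type homogeneity and tallies", {
  ts <- make_test_state()
  st <- ts$state
  mcmc_sweep(st, n_sweeps = 5, mode = "accept-all")
  pmap <- state_partition(st)
  # every block holds exactly one node type
  mix <- tapply(pmap$type, pmap$block, function(x) length(unique(x)))
  expect_true(all(mix == 1))
  # sum of block degrees = 2E
  info <- sctopics:::cpp_state_block_info(st$ptr)
  expect_equal(sum(info$e_total), 2 * ts$graph$E)
  expect_equal(sctopics:::cpp_state_dl(st$ptr),
               sctopics:::cpp_state_recompute_dl(st$ptr), tolerance = 1e-9)
})

test_that("MH sweeps lower Sigma on strongly planted graphs", {
  worked <- vapply(1:10, function(seed) {
    sim <- simulate_planted_bipartite(n_cells = 40, n_genes = 20,
                                      n_blocks = 2, signal = 10, seed = seed)
    g <- build_graph(sim$layer)
    types <- sctopics:::graph_type_codes(g)
    part <- withr::with_seed(seed, sctopics:::random_typed_partition(types))
    st <- sbm_state(g, part, seed = seed)
    s0 <- sctopics:::cpp_state_dl(st$ptr)
    mcmc_sweep(st, n_sweeps = 50, beta = 1)
    sctopics:::cpp_state_dl(st$ptr) < s0
  }, logical(1))
  expect_gte(mean(worked), 0.95)
})

test_that("fits are reproducible, best-of-n, and hierarchically consistent", {
  sim <- simulate_planted_bipartite(n_cells = 40, n_genes = 30, n_blocks = 3,
                                    seed = 4)
  g <- build_graph(sim$layer)
  fit1 <- fit_sbm(g, n_init = 3, seed = 123)
  fit2 <- fit_sbm(g, n_init = 3, seed = 123)
  expect_identical(fit1$memberships, fit2$memberships)
  expect_identical(fit1$sigma, fit2$sigma)

  expect_equal(fit1$sigma, min(fit1$init_sigmas))
  expect_true(all(fit1$init_sigmas >= fit1$sigma - 1e-9))

  # refinement: each level is a coarsening of the one below
  m <- fit1$memberships
  for (l in seq_len(ncol(m) - 1)) {
    mapping <- tapply(m[, l + 1], m[, l], function(x) length(unique(x)))
    expect_true(all(mapping == 1))
  }
  # block counts never increase with level
  counts <- fit1$levels |> dplyr::group_by(type) |>
    dplyr::summarise(mono = all(diff(n_blocks) <= 0))
  expect_true(all(counts$mono))
  # top level: one block per type
  expect_equal(max(m[, ncol(m)]), 2)
})

test_that("single-node-per-type graphs degrade gracefully", {
  g <- build_graph(count_layer(matrix(3, 1, 1), genes = "g", cells = "c"))
  expect_warning(fit <- fit_sbm(g, n_init = 1, seed = 1), "single")
  expect_equal(ncol(fit$memberships), 1)
})

test_that("exhaustive enumeration confirms the fitted minimum on tiny graphs", {
  for (g in tiny_fixture_graphs()) {
    enum <- enumerate_min_dl(g)
    fit <- fit_sbm(g, n_init = 7, seed = 99)
    expect_equal(fit$sigma, enum$sigma, tolerance = 1e-9)
  }
})
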