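pc_tbl <- function(mat) {
  # clusters x topics matrix -> long centered-table format
  tibble::tibble(
    cluster = rep(seq_len(nrow(mat)), ncol(mat)),
    topic = rep(seq_len(ncol(mat)), each = nrow(mat)),
    pc = as.numeric(mat))
}

test_that("centering removes per-topic means and per-cell sums", {
  tab <- tibble::tibble(cell = rep(c("a", "b"), each = 2),
                        topic = rep(1:2, 2),
                        prob = c(0.8, 0.2, 0.4, 0.6))
  pc <- center_topic_distribution(tab)
  expect_equal(pc$pc[pc$cell == "a"], c(0.2, -0.2))
  expect_equal(pc$pc[pc$cell == "b"], c(-0.2, 0.2))

  # identical cells -> identically zero
  same <- tibble::tibble(cell = rep(c("a", "b"), each = 2),
                         topic = rep(1:2, 2), prob = rep(c(0.7, 0.3), 2))
  expect_true(all(center_topic_distribution(same)$pc == 0))

  # random tables: per-topic means vanish, per-cell sums vanish
  withr::local_seed(3)
  p <- matrix(rexp(60), nrow = 10)
  p <- p / rowSums(p)
  rand <- tibble::tibble(cell = rep(paste0("c", 1:10), 6),
                         topic = rep(1:6, each = 10), prob = as.numeric(p))
  pcr <- center_topic_distribution(rand)
  expect_true(all(abs(tapply(pcr$pc, pcr$topic, mean)) < 1e-12))
  expect_true(all(abs(tapply(pcr$pc, pcr$cell, sum)) < 1e-12))

  expect_error(center_topic_distribution(tab[0, ]), "empty")
})

test_that("cluster means aggregate centered probabilities", {
  tab <- tibble::tibble(cell = rep(c("a", "b"), each = 2),
                        topic = rep(1:2, 2),
                        prob = c(0.8, 0.2, 0.4, 0.6))
  pc <- center_topic_distribution(tab)
  # both cells in one cluster: the means cancel
  one <- cluster_topic_probability(pc, tibble::tibble(cell = c("a", "b"),
                                                      cluster = 1))
  expect_equal(one$pc, c(0, 0))
  # singleton clusters reproduce the cells' own rows
  two <- cluster_topic_probability(pc, tibble::tibble(cell = c("a", "b"),
                                                      cluster = 1:2))
  expect_equal(dplyr::arrange(two, cluster, topic)$pc,
               c(0.2, -0.2, -0.2, 0.2))
  # unmapped cells are an error
  expect_error(cluster_topic_probability(pc, tibble::tibble(cell = "a",
                                                            cluster = 1)),
               "missing")
  # random group-by-mean oracle
  withr::local_seed(8)
  pcr <- tibble::tibble(cell = rep(paste0("c", 1:12), 4),
                        topic = rep(1:4, each = 12), pc = rnorm(48))
  cl <- tibble::tibble(cell = paste0("c", 1:12),
                       cluster = rep(1:3, each = 4))
  got <- cluster_topic_probability(pcr, cl)
  for (i in seq_len(nrow(got))) {
    cells_in <- cl$cell[cl$cluster == got$cluster[i]]
    expect_equal(got$pc[i],
                 mean(pcr$pc[pcr$cell %in% cells_in &
                               pcr$topic == got$topic[i]]),
                 tolerance = 1e-12)
  }
})

test_that("the adaptive threshold terminates where the reference loop does", {
  # single cluster [0.9, -0.3, -0.3, -0.3]: population sigma = sqrt(0.27),
  # first non-empty assignment at n = 1.70 with topic set {T1}
  m1 <- matrix(c(0.9, -0.3, -0.3, -0.3), nrow = 1)
  res1 <- assign_topics_to_clusters(pc_tbl(m1))
  expect_equal(res1$n, 1.70, tolerance = 1e-9)
  expect_equal(res1$assignment$topic, 1)
  ref1 <- oracle_assign(m1)
  expect_equal(res1$n, ref1$n, tolerance = 1e-9)
  expect_equal(res1$assignment$topic, ref1$sets[[1]])

  # antisymmetric pair: sigma = 1, threshold first satisfied at n = 0.95
  m2 <- rbind(c(1, -1), c(-1, 1))
  res2 <- assign_topics_to_clusters(pc_tbl(m2))
  expect_equal(res2$n, 0.95, tolerance = 1e-9)
  sets2 <- split(res2$assignment$topic, res2$assignment$cluster)
  expect_equal(sets2, list(`1` = 1L, `2` = 2L), ignore_attr = TRUE)

  # identical rows can never be told apart
  m3 <- rbind(c(0.5, -0.5), c(0.5, -0.5))
  expect_error(assign_topics_to_clusters(pc_tbl(m3)), "identical topic sets")
})

test_that("adaptive assignment matches the reference loop on random tables", {
  withr::local_seed(12)
  for (rep in 1:20) {
    m <- matrix(rnorm(5 * 8), nrow = 5)
    m <- m - rowMeans(m)
    ref <- oracle_assign(m)
    if (is.null(ref)) {
      expect_error(assign_topics_to_clusters(pc_tbl(m)))
    } else {
      got <- assign_topics_to_clusters(pc_tbl(m))
      expect_equal(got$n, ref$n, tolerance = 1e-9)
      got_sets <- split(got$assignment$topic, got$assignment$cluster)
      expect_equal(unname(got_sets), unname(ref$sets), ignore_attr = TRUE)
    }
  }
})

test_that("topic sets only grow as n decreases and survive relabeling", {
  withr::local_seed(44)
  m <- matrix(rnorm(4 * 6), nrow = 4)
  tab <- pc_tbl(m)
  stats <- tab |> dplyr::group_by(cluster) |>
    dplyr::summarise(mu = mean(pc), sigma = sqrt(mean((pc - mean(pc))^2)))
  prev <- NULL
  for (n in seq(3, 0, by = -0.05)) {
    sel <- dplyr::inner_join(tab, stats, by = "cluster") |>
      dplyr::filter(pc > mu + n * sigma)
    cur <- paste(sel$cluster, sel$topic)
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }

  # relabeling topics and clusters permutes but does not change the result
  res <- assign_topics_to_clusters(pc_tbl(m))
  perm_t <- sample(6); perm_c <- sample(4)
  tab2 <- pc_tbl(m) |>
    dplyr::mutate(topic = perm_t[topic], cluster = perm_c[cluster])
  res2 <- assign_topics_to_clusters(tab2)
  expect_equal(res2$n, res$n)
  s1 <- lapply(split(res$assignment$topic, res$assignment$cluster), sort)
  s2 <- lapply(split(res2$assignment$topic, res2$assignment$cluster), sort)
  for (k in seq_len(4)) {
    expect_equal(sort(perm_t[s1[[as.character(k)]]]),
                 s2[[as.character(perm_c[k])]])
  }
})

test_that("assignment runs on arbitrary cell partitions from a real fit", {
  sim <- simulate_planted_bipartite(n_cells = 40, n_genes = 24, n_blocks = 3,
                                    seed = 21)
  g <- build_graph(sim$layer)
  fit <- fit_sbm(g, n_init = 3, seed = 21)
  # the model's own clusters
  res <- assign_topics(fit, level = 0)
  expect_s3_class(res, "cluster_topic_assignment")
  expect_true(all(table(res$assignment$cluster) >= 1))
  # an external partition: the planted groups
  custom <- dplyr::rename(sim$cell_groups, cluster = group)
  res2 <- assign_topics(fit, level = 0, clusters = custom)
  expect_setequal(unique(res2$assignment$cluster),
                  unique(custom$cluster))
})
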