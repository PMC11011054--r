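toy_collection <- function() {
  # 100 distinct genes; one oversized set of 16, one boundary set of 15
  sets <- list(
    big16 = paste0("g", 1:16),
    edge15 = paste0("g", 17:31),
    small = paste0("g", 32:41),
    tiny = paste0("g", 42:44)
  )
  extra <- split(paste0("g", 45:100), rep(1:4, length.out = 56))
  names(extra) <- paste0("fill", 1:4)
  gene_set_collection(c(sets, extra), "toy")
}

test_that("the collection-ratio filter removes sets strictly above the cutoff", {
  col <- toy_collection()
  expect_equal(col$total_genes, 100)
  kept <- filter_gene_sets(col, max_ratio = 0.15)
  expect_false("big16" %in% names(kept$sets))   # 0.16 > 0.15
  expect_true("edge15" %in% names(kept$sets))   # 0.15 is not > 0.15
  # identity at ratio 1, and filtered collections are subsets
  all_kept <- filter_gene_sets(col, max_ratio = 1)
  expect_identical(all_kept$sets, col$sets)
  expect_true(all(names(kept$sets) %in% names(col$sets)))
  expect_warning(empty <- filter_gene_sets(col, max_ratio = 0.001),
                 "filtered out")
  expect_length(empty$sets, 0)
})

test_that("hypergeometric p-values equal exhaustive tail sums", {
  universe <- paste0("u", 1:10)
  col <- gene_set_collection(list(S = universe[1:5]), "c")
  # N = 10, K = 5, n = 4, k = 4: 5 / C(10, 4)
  res <- hypergeometric_enrich(universe[c(1:4)], col, universe)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_hyper_tail(10, 5, 4, 4), tolerance = 1e-12)
  # zero overlap -> p = 1
  res0 <- hypergeometric_enrich(universe[6:9], col, universe)
  expect_equal(res0$p_value, 1)
  expect_error(hypergeometric_enrich("a", col, character(0)), "universe")
})

test_that("random instances match the brute-force tail oracle", {
  withr::local_seed(41)
  genes <- paste0("g", 1:60)
  for (i in 1:25) {
    universe <- sample(genes, sample(20:60, 1))
    set <- sample(genes, sample(5:30, 1))
    topic <- sample(universe, sample(3:15, 1))
    col <- gene_set_collection(list(S = set), "c")
    res <- hypergeometric_enrich(topic, col, universe)
    N <- length(universe)
    K <- length(intersect(set, universe))
    n <- length(intersect(topic, universe))
    k <- length(intersect(intersect(set, topic), universe))
    expect_equal(res$p_value, oracle_hyper_tail(N, K, n, k),
                 tolerance = 1e-12)
    # permuting identifiers leaves the p-value unchanged
    perm <- setNames(sample(genes), genes)
    res_p <- hypergeometric_enrich(unname(perm[topic]),
                                   gene_set_collection(
                                     list(S = unname(perm[set])), "c"),
                                   unname(perm[universe]))
    expect_equal(res_p$p_value, res$p_value, tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::local_seed(51)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH controls the false discovery proportion on null p-values", {
  withr::local_seed(60)
  fdp <- replicate(200, {
    p <- c(runif(90), rbeta(10, 0.05, 1))  # 90 nulls, 10 signals
    q <- bh_adjust(p)
    disc <- which(q <= 0.1)
    if (length(disc) == 0) 0 else mean(disc <= 90)
  })
  expect_lte(mean(fdp), 0.1 + 0.03)
})

test_that("topic summaries keep the lowest-FDR set and dedup across topics", {
  res <- tibble::tibble(
    topic = c("T1", "T1", "T2", "T2"),
    set = c("G", "H", "G", "K"),
    overlap = c(5, 4, 5, 3),
    q_value = c(0.001, 0.02, 0.01, 0.03))
  out <- summarize_topic_annotations(res, fdr_threshold = 0.05)
  expect_equal(out$set[out$topic == "T1"], "G")
  expect_equal(out$set[out$topic == "T2"], "K")  # falls back past taken G

  # a single significant set annotates its topic
  one <- tibble::tibble(topic = "T1", set = "S", overlap = 2, q_value = 0.01)
  expect_equal(summarize_topic_annotations(one)$set, "S")

  # nothing significant -> unannotated
  none <- tibble::tibble(topic = "T1", set = "S", overlap = 2, q_value = 0.5)
  expect_true(is.na(summarize_topic_annotations(none)$set))
})

test_that("dedup matches a round-based oracle on random q tables", {
  withr::local_seed(71)
  for (rep in 1:15) {
    n_topics <- sample(2:6, 1)
    n_sets <- sample(3:8, 1)
    res <- expand.grid(topic = paste0("T", 1:n_topics),
                       set = paste0("S", 1:n_sets),
                       stringsAsFactors = FALSE)
    res$overlap <- sample(1:20, nrow(res), replace = TRUE)
    res$q_value <- round(runif(nrow(res)), 3)
    got <- summarize_topic_annotations(tibble::as_tibble(res),
                                       fdr_threshold = 0.3)
    # oracle: iterate rounds; every unlabeled topic claims its best
    # remaining set; conflicts resolved by smallest q (overlap, name)
    remaining <- res[res$q_value <= 0.3, ]
    remaining <- remaining[order(remaining$q_value, -remaining$overlap,
                                 remaining$set), ]
    label <- setNames(rep(NA_character_, n_topics), paste0("T", 1:n_topics))
    taken <- character(0)
    repeat {
      open <- names(label)[is.na(label)]
      cand <- remaining[remaining$topic %in% open &
                          !(remaining$set %in% taken), ]
      if (nrow(cand) == 0) break
      best <- cand[!duplicated(cand$topic), ]       # each topic's best
      best <- best[order(best$q_value, -best$overlap, best$set), ]
      winner <- best[!duplicated(best$set), ]       # lowest q keeps the set
      winner <- winner[1, , drop = FALSE]           # settle one per round
      label[winner$topic] <- winner$set
      taken <- c(taken, winner$set)
    }
    expect_equal(setNames(got$set, got$topic), label)
  }
})
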