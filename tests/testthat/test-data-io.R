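test_that("mtx triplet layers read back exactly as stored", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.mtx")
  m <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 2, 1), x = c(5, 3, 1),
                            dims = c(3, 2))
  Matrix::writeMM(m, path)
  writeLines(c("g1", "g2", "g3"), file.path(dir, "toy_genes.txt"))
  writeLines(c("c1", "c2"), file.path(dir, "toy_cells.txt"))
  layer <- read_count_layer(path, "mtx-triplet")
  expect_equal(unname(Matrix::colSums(layer$counts)), c(6, 3))
  expect_equal(layer$genes, c("g1", "g2", "g3"))

  # stored transposed: orientation recovered from name-file lengths
  path2 <- file.path(dir, "toy2.mtx")
  Matrix::writeMM(Matrix::t(m), path2)
  writeLines(c("g1", "g2", "g3"), file.path(dir, "toy2_genes.txt"))
  writeLines(c("c1", "c2"), file.path(dir, "toy2_cells.txt"))
  layer2 <- read_count_layer(path2, "mtx-triplet")
  expect_equal(as.matrix(layer2$counts), as.matrix(layer$counts))

  # square matrices with equal-length name files are ambiguous
  path3 <- file.path(dir, "sq.mtx")
  Matrix::writeMM(m[1:2, ], path3)
  writeLines(c("g1", "g2"), file.path(dir, "sq_genes.txt"))
  writeLines(c("c1", "c2"), file.path(dir, "sq_cells.txt"))
  expect_error(read_count_layer(path3, "mtx-triplet"), "ambiguous")

  # dimension mismatch
  writeLines(c("g1", "g2", "g3", "g4"), file.path(dir, "toy_genes.txt"))
  expect_error(read_count_layer(path, "mtx-triplet"), "mismatch")
})

test_that("count layer invariants are enforced", {
  m <- matrix(1:6, nrow = 3)
  expect_error(count_layer(m, genes = c("a", "a", "b"), cells = c("c1", "c2")),
               "duplicate gene")
  expect_error(count_layer(m, genes = c("a", "b", "c"), cells = c("c1", "c1")),
               "duplicate cell")
  expect_error(count_layer(-m, genes = c("a", "b", "c"), cells = c("c1", "c2")),
               "non-negative")
  expect_error(count_layer(m, genes = c("a", "b"), cells = c("c1", "c2")),
               "lengths")
})

test_that("random layers survive a write/read round trip unchanged", {
  withr::local_seed(421)
  dir <- withr::local_tempdir()
  m <- matrix(rpois(200, 2), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  layer <- count_layer(m, layer_name = "rt")
  write_count_layer(layer, file.path(dir, "rt.mtx"))
  back <- read_count_layer(file.path(dir, "rt.mtx"), "mtx-triplet")
  expect_identical(as.matrix(back$counts), as.matrix(layer$counts))
  expect_identical(back$genes, layer$genes)
  expect_identical(back$cells, layer$cells)
})

test_that("delimited matrices load genes x cells", {
  dir <- withr::local_tempdir()
  tab <- data.frame(gene = c("g1", "g2"), c1 = c(1, 0), c2 = c(2, 4))
  path <- file.path(dir, "dense.tsv")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  layer <- read_count_layer(path, "delimited")
  expect_equal(dim(layer), c(2L, 2L))
  expect_equal(as.numeric(layer$counts["g2", "c2"]), 4)
})

test_that("GMT collections parse with union totals and validation", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  writeLines(c("A\tdesc\tg1\tg2", "B\tdesc\tg2\tg3"), path)
  col <- read_gene_sets(path)
  expect_length(col$sets, 2)
  expect_equal(col$total_genes, 3)

  writeLines("S\tdesc\tg9", path)
  single <- read_gene_sets(path)
  expect_equal(lengths(single$sets), c(S = 1L))

  writeLines(c("A\td\tg1", "A\td\tg2"), path)
  expect_error(read_gene_sets(path), "duplicate")

  writeLines(c("A\td\tg1", "E\td"), path)
  expect_warning(col2 <- read_gene_sets(path), "empty")
  expect_length(col2$sets, 1)
})

test_that("random GMT unions match a brute-force count", {
  withr::local_seed(99)
  dir <- withr::local_tempdir()
  genes <- paste0("gene", 1:200)
  sets <- lapply(1:50, function(i) sample(genes, sample(3:30, 1)))
  names(sets) <- paste0("set", 1:50)
  path <- file.path(dir, "rand.gmt")
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  col <- read_gene_sets(path)
  expect_equal(col$total_genes, length(unique(unlist(sets))))
})

test_that("results directories hold round-trippable tables and metadata", {
  withr::local_seed(7)
  sim <- simulate_planted_bipartite(n_cells = 30, n_genes = 20, n_blocks = 2,
                                    seed = 3)
  fit <- fit_sbm(build_graph(sim$layer), n_init = 2, seed = 3)
  res <- topic_model_result(fit, level = 0)
  out <- file.path(withr::local_tempdir(), "nested", "run1")
  manifest <- write_results(res, out, run_info = list(seed = 3, n_init = 2))
  expect_true(dir.exists(out))
  expect_gte(length(manifest), 4)
  expect_true(all(file.exists(manifest)))

  gt_back <- readr::read_tsv(
    file.path(out, "L0_gene_topic_planted.tsv"), show_col_types = FALSE)
  expect_equal(gt_back$prob, res$gene_topic$planted$prob, tolerance = 1e-12)
  tc_back <- readr::read_tsv(
    file.path(out, "L0_topic_cell_planted.tsv"), show_col_types = FALSE)
  expect_equal(tc_back$prob, res$topic_cell$planted$prob, tolerance = 1e-12)
  meta <- jsonlite::read_json(file.path(out, "run_metadata.json"))
  expect_equal(meta$seed, 3)
})
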