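#' Construct a count layer
#'
#' A count layer is one omics layer of a single-cell experiment: a genes x
#' cells matrix of non-negative counts with unique gene and cell
#' identifiers. Layers that share the same cells (e.g. mRNA and lncRNA
#' counts from the same experiment) can be combined into a multipartite
#' gene-cell graph with [build_graph()].
#'
#' @param counts A genes x cells matrix (dense or `Matrix` sparse) of
#'   non-negative counts.
#' @param genes Character vector of gene identifiers (rows). Defaults to
#'   `rownames(counts)`.
#' @param cells Character vector of cell identifiers (columns). Defaults to
#'   `colnames(counts)`.
#' @param layer_name Text label for the layer, e.g. `"mRNA"`.
#'
#' @return An object of class `count_layer` with fields `layer_name`,
#'   `genes`, `cells` and the sparse `counts` matrix.
#' @export
count_layer <- function(counts, genes = rownames(counts),
                        cells = colnames(counts), layer_name = "layer") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(genes)) stop("gene identifiers are required", call. = FALSE)
  if (is.null(cells)) stop("cell identifiers are required", call. = FALSE)
  genes <- as.character(genes)
  cells <- as.character(cells)
  if (length(genes) != nrow(counts) || length(cells) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cells))
    stop("duplicate cell identifiers: ",
         paste(unique(cells[duplicated(cells)]), collapse = ", "),
         call. = FALSE)
  if (any(counts@x < 0))
    stop("counts must be non-negative", call. = FALSE)
  dimnames(counts) <- list(genes, cells)
  structure(
    list(layer_name = layer_name, genes = genes, cells = cells,
         counts = counts),
    class = "count_layer"
  )
}

#' @export
print.count_layer <- function(x, ...) {
  cat(sprintf("<count_layer '%s': %d genes x %d cells, %d non-zero entries>\n",
              x$layer_name, length(x$genes), length(x$cells),
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.count_layer <- function(x) dim(x$counts)

#' Tidy a count layer into a long tibble
#'
#' Returns the non-zero entries as a long `(gene, cell, count)` tibble,
#' convenient for dplyr-style summaries.
#'
#' @param x A [count_layer()].
#' @param ... Unused.
#' @return A tibble with columns `gene`, `cell`, `count`.
#' @method tidy count_layer
#' @export
tidy.count_layer <- function(x, ...) {
  m <- methods::as(x$counts, "TsparseMatrix")
  tibble::tibble(
    gene = x$genes[m@i + 1L],
    cell = x$cells[m@j + 1L],
    count = m@x
  )
}

#' Read a count layer from disk
#'
#' Supports two plain-text formats: Matrix Market triplets
#' (`format = "mtx-triplet"`, with companion `<stem>_genes.txt` and
#' `<stem>_cells.txt` name files, one identifier per line) and dense
#' delimited tables (`format = "delimited"`, genes in rows with identifiers
#' in the first column, cell identifiers in the header).
#'
#' For the triplet format the stored orientation is auto-detected from the
#' name-file lengths: whichever name file matches the matrix row count
#' labels the rows. A square matrix with equal-length name files is
#' ambiguous and raises an error.
#'
#' @param path Path to the `.mtx` file or the delimited table.
#' @param format `"mtx-triplet"` or `"delimited"`.
#' @param layer_name Label for the layer; defaults to the file stem.
#' @param delim Field delimiter for `format = "delimited"`; `NULL` guesses
#'   tab for `.tsv`/`.txt` and comma for `.csv`.
#'
#' @return A [count_layer()], oriented genes x cells.
#' @export
read_count_layer <- function(path, format = c("mtx-triplet", "delimited"),
                             layer_name = NULL, delim = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stem <- sub("\\.[^.]*$", "", path)
  if (is.null(layer_name)) layer_name <- basename(stem)
  if (format == "mtx-triplet") {
    gene_file <- paste0(stem, "_genes.txt")
    cell_file <- paste0(stem, "_cells.txt")
    if (!file.exists(gene_file) || !file.exists(cell_file))
      stop("companion name files not found: expected ", gene_file, " and ",
           cell_file, call. = FALSE)
    m <- Matrix::readMM(path)
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      if (nrow(m) == ncol(m) && length(genes) == length(cells))
        stop("orientation ambiguous: square matrix with equal-length name files",
             call. = FALSE)
    } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      m <- Matrix::t(m)
    } else {
      stop("dimension mismatch between matrix (", nrow(m), " x ", ncol(m),
           ") and name files (", length(genes), " genes, ", length(cells),
           " cells)", call. = FALSE)
    }
    count_layer(m, genes = genes, cells = cells, layer_name = layer_name)
  } else {
    if (is.null(delim))
      delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    count_layer(m, genes = genes, cells = colnames(m), layer_name = layer_name)
  }
}

#' Write a count layer as Matrix Market triplets
#'
#' Writes `<stem>.mtx` plus `<stem>_genes.txt` and `<stem>_cells.txt`
#' companion name files, the representation [read_count_layer()] reads back.
#'
#' @param layer A [count_layer()].
#' @param path Path to the `.mtx` file to create.
#' @return Invisibly, the paths written.
#' @export
write_count_layer <- function(layer, path) {
  stopifnot(inherits(layer, "count_layer"))
  stem <- sub("\\.[^.]*$", "", path)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(layer$counts, path)
  gene_file <- paste0(stem, "_genes.txt")
  cell_file <- paste0(stem, "_cells.txt")
  writeLines(layer$genes, gene_file)
  writeLines(layer$cells, cell_file)
  invisible(c(path, gene_file, cell_file))
}
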