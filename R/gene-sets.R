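#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-separated format used by MSigDB-style databases: one set
#' per line as `name<TAB>description<TAB>member1<TAB>member2...`. Parsing is
#' delegated to [fgsea::gmtPathways()]; this wrapper adds the validation the
#' downstream enrichment steps rely on: duplicated set names are an error,
#' sets with no members are dropped with a warning, and duplicated members
#' within a set are collapsed.
#'
#' @param path Path to a GMT file.
#' @param collection_name Label for the collection; defaults to the file
#'   stem. Large databases group sets into collections, and set-size
#'   filtering ([filter_gene_sets()]) is relative to the collection.
#'
#' @return An object of class `gene_set_collection`: a list with
#'   `collection_name`, `sets` (named list of character vectors) and
#'   `total_genes` (size of the union of all sets).
#' @export
read_gene_sets <- function(path, collection_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(collection_name))
    collection_name <- sub("\\.[^.]*$", "", basename(path))
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in ", path, ": ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  sets <- lapply(sets, function(g) unique(g[!is.na(g) & nzchar(g)]))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("skipping ", sum(empty), " empty gene set(s): ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  gene_set_collection(sets, collection_name)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param collection_name Text label.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, collection_name = "collection") {
  if (length(sets) > 0 && (is.null(names(sets)) || any(!nzchar(names(sets)))))
    stop("all gene sets must be named", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names", call. = FALSE)
  if (any(lengths(sets) == 0))
    stop("gene sets must be non-empty", call. = FALSE)
  structure(
    list(collection_name = collection_name,
         sets = sets,
         total_genes = length(unique(unlist(sets, use.names = FALSE)))),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection '%s': %d sets over %d distinct genes>\n",
              x$collection_name, length(x$sets), x$total_genes))
  invisible(x)
}

#' Tidy a gene-set collection into a long tibble
#'
#' @param x A `gene_set_collection`.
#' @param ... Unused.
#' @return A tibble with columns `set`, `gene`.
#' @method tidy gene_set_collection
#' @export
tidy.gene_set_collection <- function(x, ...) {
  tibble::tibble(
    set = rep(names(x$sets), lengths(x$sets)),
    gene = unlist(x$sets, use.names = FALSE)
  )
}
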