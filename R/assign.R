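#' Center a topic-by-cell probability table
#'
#' Subtracts each topic's mean probability over cells:
#' `Pc(T | c) = P(T | c) - mean_c' P(T | c')`. The centered table is more
#' informative than the raw one because it highlights cells that use a
#' topic more than the average cell. After centering, each topic's mean
#' over cells is 0 and (since each cell's row summed to 1) each cell's sum
#' over topics is 0.
#'
#' @param data A long tibble with columns `cell`, `topic` and `prob`
#'   (rows of `prob` per cell sum to 1), e.g. from
#'   [topic_cell_distribution()]. Missing cell-topic pairs are treated as
#'   probability 0. Zero-degree rows (`topic = NA`) are dropped.
#' @return A long tibble `cell`, `topic`, `pc` dense over all
#'   cell-by-topic combinations.
#' @export
center_topic_distribution <- function(data) {
  stopifnot(all(c("cell", "topic", "prob") %in% names(data)))
  data <- dplyr::filter(data, !is.na(.data$topic))
  if (nrow(data) == 0) stop("empty probability table", call. = FALSE)
  data |>
    tidyr::complete(.data$cell, .data$topic, fill = list(prob = 0)) |>
    dplyr::group_by(.data$topic) |>
    dplyr::mutate(pc = .data$prob - mean(.data$prob)) |>
    dplyr::ungroup() |>
    dplyr::select("cell", "topic", "pc")
}

#' Mean centered probability per cluster
#'
#' `Pc(T | K) = mean over cells of cluster K of Pc(T | cell)` — the average
#' centered topic usage inside each cell cluster (or any other cell
#' partition, e.g. known subtype labels).
#'
#' @param pc A centered table from [center_topic_distribution()] (columns
#'   `cell`, `topic`, `pc`).
#' @param clusters A tibble mapping `cell` to `cluster`, e.g. from
#'   [cell_clusters()]. Every cell in `pc` must appear.
#' @return A tibble `cluster`, `topic`, `pc`.
#' @export
cluster_topic_probability <- function(pc, clusters) {
  stopifnot(all(c("cell", "topic", "pc") %in% names(pc)),
            all(c("cell", "cluster") %in% names(clusters)))
  missing <- setdiff(unique(pc$cell), clusters$cell)
  if (length(missing) > 0)
    stop("cells missing from the cluster map: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  dplyr::inner_join(pc, clusters, by = "cell") |>
    dplyr::group_by(.data$cluster, .data$topic) |>
    dplyr::summarise(pc = mean(.data$pc), .groups = "drop")
}

#' Adaptive assignment of topics to clusters
#'
#' Each cluster receives the topics whose centered probability stands out:
#' topic `T` is assigned to cluster `K` when
#' `Pc(T | K) > mu_K + n * sigma_K`, with `mu_K` and `sigma_K` the mean and
#' (population) standard deviation of `Pc(. | K)` across topics. The
#' threshold multiplier `n` is chosen adaptively: starting from
#' `n_start = 3` it is lowered in steps of 0.05 until (i) every cluster has
#' at least one topic and (ii) no two clusters have identical topic sets
#' (proper subsets are allowed). Because lowering `n` only loosens the
#' thresholds, topic sets grow monotonically along the grid and the first
#' `n` satisfying both conditions is the final one.
#'
#' If the conditions cannot be met by `n = 0` (e.g. two clusters with
#' identical centered profiles) the procedure fails with an error naming
#' the offending clusters rather than guessing an assignment.
#'
#' @param pc_cluster A `cluster` x `topic` centered table from
#'   [cluster_topic_probability()]. With a multipartite fit, concatenate
#'   the layers' tables (topics relabelled uniquely, e.g. "mRNA:3"); mu and
#'   sigma are then computed across the topics of all layers.
#' @param n_start Starting threshold multiplier (default 3).
#' @param step Grid step for lowering `n` (default 0.05).
#' @return An object of class `cluster_topic_assignment`: list with
#'   `assignment` (tibble `cluster`, `topic`, `pc`), `n` (final
#'   multiplier), `stats` (per-cluster `mu`, `sigma`) and `pc_cluster`.
#' @export
assign_topics_to_clusters <- function(pc_cluster, n_start = 3, step = 0.05) {
  stopifnot(all(c("cluster", "topic", "pc") %in% names(pc_cluster)))
  clusters <- unique(pc_cluster$cluster)
  topics <- unique(pc_cluster$topic)
  if (length(topics) < 2) stop("at least 2 topics are required", call. = FALSE)

  stats_tbl <- pc_cluster |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      mu = mean(.data$pc),
      sigma = sqrt(mean((.data$pc - mean(.data$pc))^2)),
      .groups = "drop")

  with_stats <- dplyr::left_join(pc_cluster, stats_tbl, by = "cluster")

  # walk the n grid downwards; sets only grow, stop at the first n that works
  n_grid <- seq(n_start, 0, by = -step)
  if (n_grid[length(n_grid)] > 1e-12) n_grid <- c(n_grid, 0)
  for (n in n_grid) {
    sel <- dplyr::filter(with_stats, .data$pc > .data$mu + n * .data$sigma)
    ok_nonempty <- all(clusters %in% sel$cluster)
    if (!ok_nonempty) next
    sets <- split(sel$topic, sel$cluster)
    keys <- vapply(sets, function(s) paste(sort(s), collapse = "\r"),
                   character(1))
    if (anyDuplicated(keys) == 0) {
      return(structure(
        list(assignment = dplyr::select(sel, "cluster", "topic", "pc"),
             n = n, stats = stats_tbl, pc_cluster = pc_cluster),
        class = "cluster_topic_assignment"))
    }
  }
  # diagnose the failure at n = 0
  sel <- dplyr::filter(with_stats, .data$pc > .data$mu)
  sets <- split(sel$topic, sel$cluster)
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "\r"), character(1))
  dup <- names(keys)[keys %in% keys[duplicated(keys)]]
  empty <- setdiff(as.character(clusters), names(sets))
  stop("no threshold multiplier in [0, ", n_start, "] satisfies the ",
       "assignment conditions",
       if (length(dup)) paste0("; clusters with identical topic sets: ",
                               paste(dup, collapse = ", ")),
       if (length(empty)) paste0("; clusters with no topic: ",
                                 paste(empty, collapse = ", ")),
       call. = FALSE)
}

#' @export
print.cluster_topic_assignment <- function(x, ...) {
  cat(sprintf("<cluster_topic_assignment: %d clusters, final n = %.2f>\n",
              nrow(x$stats), x$n))
  print(x$assignment, n = 20)
  invisible(x)
}

#' @method tidy cluster_topic_assignment
#' @export
tidy.cluster_topic_assignment <- function(x, ...) {
  dplyr::left_join(x$assignment, x$stats, by = "cluster") |>
    dplyr::mutate(n = x$n)
}

#' @method glance cluster_topic_assignment
#' @export
glance.cluster_topic_assignment <- function(x, ...) {
  tibble::tibble(n = x$n,
                 n_clusters = nrow(x$stats),
                 n_topics_assigned = length(unique(x$assignment$topic)),
                 mean_set_size = nrow(x$assignment) / nrow(x$stats))
}

#' Full assignment pipeline from a fitted model
#'
#' Centers each layer's topic-cell table, concatenates the layers with
#' unique topic labels (`"<layer>:<topic>"`), averages within the model's
#' cell clusters at the same level, and runs the adaptive assignment.
#'
#' @inheritParams gene_topic_distribution
#' @param clusters Optional custom cell partition (`cell`, `cluster`
#'   tibble); defaults to the model's clusters at `level`. Any partition
#'   works, e.g. known subtype labels.
#' @param n_start,step Passed to [assign_topics_to_clusters()].
#' @return A `cluster_topic_assignment`.
#' @export
assign_topics <- function(fit, level = 0, clusters = NULL, n_start = 3,
                          step = 0.05) {
  stopifnot(inherits(fit, "sbm_fit"))
  if (is.null(clusters)) clusters <- cell_clusters(fit, level)
  pc_all <- purrr::map(fit$graph$layers, function(l) {
    topic_cell_distribution(fit, level, l) |>
      dplyr::filter(!is.na(.data$topic)) |>
      dplyr::mutate(topic = paste0(l, ":", .data$topic)) |>
      center_topic_distribution()
  }) |> purrr::list_rbind()
  pc_cluster <- cluster_topic_probability(pc_all, clusters)
  assign_topics_to_clusters(pc_cluster, n_start = n_start, step = step)
}
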