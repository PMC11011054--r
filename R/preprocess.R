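#' Library-size normalization
#'
#' Rescales each cell so its total count equals `target_sum`, preserving the
#' within-cell proportions. Cells whose total count is zero cannot be
#' rescaled and are dropped with a warning.
#'
#' @param layer A [count_layer()].
#' @param target_sum Positive number every cell's column should sum to
#'   (default `1e4`, the conventional counts-per-ten-thousand scale).
#'
#' @return A [count_layer()] with normalized (generally non-integer) values.
#' @export
normalize_library_size <- function(layer, target_sum = 1e4) {
  stopifnot(inherits(layer, "count_layer"), target_sum > 0)
  totals <- Matrix::colSums(layer$counts)
  if (all(totals == 0)) stop("all cells have zero total count", call. = FALSE)
  if (any(totals == 0)) {
    warning("dropping ", sum(totals == 0), " cell(s) with zero total count",
            call. = FALSE)
    keep <- totals > 0
    layer <- count_layer(layer$counts[, keep, drop = FALSE],
                         genes = layer$genes, cells = layer$cells[keep],
                         layer_name = layer$layer_name)
    totals <- totals[keep]
  }
  scaled <- layer$counts %*% Matrix::Diagonal(x = target_sum / totals)
  count_layer(scaled, genes = layer$genes, cells = layer$cells,
              layer_name = layer$layer_name)
}

#' Highly variable gene selection by binned normalized dispersion
#'
#' Selects genes whose dispersion (variance/mean) stands out among genes of
#' comparable mean expression: genes are binned by mean, dispersions are
#' z-scored within each bin, and genes whose normalized dispersion exceeds
#' `min_disp` are retained. This is the classic mean-binned dispersion
#' procedure used throughout single-cell analysis; it should be applied to a
#' library-size-normalized layer.
#'
#' Bins with a single gene (or zero dispersion spread) fall back to a
#' z-score of 0 for their genes. If there are fewer distinct gene means than
#' `n_bins`, a single bin is used with a warning.
#'
#' @param layer A normalized [count_layer()] with at least 2 cells.
#' @param min_disp Threshold on the normalized dispersion (default 0.5).
#' @param n_bins Number of equal-frequency mean bins (default 20).
#'
#' @return The subset [count_layer()] of retained genes.
#' @export
select_highly_variable <- function(layer, min_disp = 0.5, n_bins = 20) {
  stopifnot(inherits(layer, "count_layer"))
  if (length(layer$cells) < 2)
    stop("at least 2 cells are required", call. = FALSE)
  disp <- normalized_dispersion(layer, n_bins = n_bins)
  # genes with zero mean have no defined dispersion; they only survive the
  # degenerate -Inf threshold (the "keep everything" bound)
  dn <- ifelse(is.na(disp$dispersion_norm), -Inf, disp$dispersion_norm)
  keep <- dn > min_disp | (is.infinite(min_disp) & min_disp < 0)
  count_layer(layer$counts[keep, , drop = FALSE],
              genes = layer$genes[keep], cells = layer$cells,
              layer_name = layer$layer_name)
}

#' Per-gene normalized dispersions
#'
#' The statistic behind [select_highly_variable()], exposed for inspection.
#'
#' @inheritParams select_highly_variable
#' @return A tibble with columns `gene`, `mean`, `dispersion` and
#'   `dispersion_norm` (the within-bin z-score).
#' @export
normalized_dispersion <- function(layer, n_bins = 20) {
  m <- layer$counts
  mu <- Matrix::rowMeans(m)
  # E[x^2] - mu^2, with the usual n/(n-1) correction
  n <- ncol(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  if (length(unique(mu[mu > 0])) < n_bins) {
    warning("fewer distinct gene means than bins; using a single bin",
            call. = FALSE)
    bins <- rep(1L, length(mu))
  } else {
    bins <- as.integer(cut(mu, breaks = unique(stats::quantile(
      mu, probs = seq(0, 1, length.out = n_bins + 1), names = FALSE)),
      include.lowest = TRUE))
  }
  tibble::tibble(gene = layer$genes, mean = mu, dispersion = disp,
                 bin = bins) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(
      dispersion_norm = {
        d <- .data$dispersion
        mu_b <- mean(d, na.rm = TRUE)
        sd_b <- stats::sd(d, na.rm = TRUE)
        if (is.na(sd_b) || sd_b == 0) ifelse(is.na(d), NA_real_, 0)
        else (d - mu_b) / sd_b
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"bin")
}
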