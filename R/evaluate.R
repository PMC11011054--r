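#' Normalized mutual information between two labelings
#'
#' Mutual information (in nats) normalized by the arithmetic mean of the
#' two label entropies: `NMI = 2 I(A; B) / (H(A) + H(B))`. It is symmetric,
#' invariant to relabeling, 1 iff the partitions are identical up to
#' relabeling and 0 for independent partitions. When either partition has
#' a single cluster its entropy is zero and NMI is defined as 0 (this keeps
#' the null-model mean of [nmi_null()] finite).
#'
#' @param labels_a,labels_b Equal-length vectors of cluster labels (any
#'   atomic type).
#' @param normalization `"mean"` (arithmetic mean of entropies, default),
#'   `"min"`, `"max"` or `"sqrt"` (geometric mean).
#' @return A value in \[0, 1\].
#' @export
nmi <- function(labels_a, labels_b,
                normalization = c("mean", "min", "max", "sqrt")) {
  normalization <- match.arg(normalization)
  if (length(labels_a) != length(labels_b))
    stop("labelings must have equal length", call. = FALSE)
  if (length(labels_a) == 0) stop("empty labelings", call. = FALSE)
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  hx <- entropy_nat(rowSums(tab) / n)
  hy <- entropy_nat(colSums(tab) / n)
  if (hx == 0 || hy == 0) return(0)
  p <- tab / n
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  denom <- switch(normalization,
    mean = (hx + hy) / 2,
    min = min(hx, hy),
    max = max(hx, hy),
    sqrt = sqrt(hx * hy))
  min(1, max(0, mi / denom))
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Null-model NMI (NMI*)
#'
#' The expected NMI between `true_labels` and random relabelings of
#' `pred_labels` that preserve the number of clusters and their sizes (the
#' labels are permuted uniformly across the samples). This is the score a
#' random classifier with the same cluster-size profile would achieve;
#' dividing the empirical NMI by it corrects the selection bias by which
#' NMI grows with the number of clusters.
#'
#' @param pred_labels Predicted cluster labels.
#' @param true_labels Ground-truth labels.
#' @param n_shuffles Number of random permutations to average over
#'   (default 100).
#' @param seed Integer seed; fixed seeds give bit-reproducible results.
#' @param normalization Passed to [nmi()].
#' @return A list with `nmi_star` (the mean), `sd` (the across-permutation
#'   standard deviation) and `n_shuffles`.
#' @export
nmi_null <- function(pred_labels, true_labels, n_shuffles = 100, seed = 1L,
                     normalization = "mean") {
  if (length(pred_labels) != length(true_labels))
    stop("labelings must have equal length", call. = FALSE)
  stopifnot(n_shuffles >= 1)
  vals <- local_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      nmi(sample(pred_labels), true_labels, normalization = normalization)
    }, numeric(1))
  })
  list(nmi_star = mean(vals), sd = stats::sd(vals), n_shuffles = n_shuffles)
}

#' Null-adjusted clustering score
#'
#' Bundles NMI, NMI* and their ratio. `NMI/NMI*` expresses how much better
#' than a size-matched random classifier the clustering agrees with the
#' ground truth; values near 1 mean the agreement is what chance alone
#' would produce.
#'
#' @inheritParams nmi_null
#' @return A one-row tibble with `nmi`, `nmi_star`, `nmi_star_sd`, `ratio`,
#'   `n_shuffles`, `seed`.
#' @export
clustering_score <- function(pred_labels, true_labels, n_shuffles = 100,
                             seed = 1L, normalization = "mean") {
  v <- nmi(pred_labels, true_labels, normalization = normalization)
  nullm <- nmi_null(pred_labels, true_labels, n_shuffles = n_shuffles,
                    seed = seed, normalization = normalization)
  tibble::tibble(
    nmi = v, nmi_star = nullm$nmi_star, nmi_star_sd = nullm$sd,
    ratio = if (nullm$nmi_star > 0) v / nullm$nmi_star else NA_real_,
    n_shuffles = n_shuffles, seed = seed)
}

#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected for chance under the permutation model and
#' normalized so identical partitions score 1:
#' `AMI = (I - E[I]) / (mean(H(A), H(B)) - E[I])`, with `E[I]` the expected
#' mutual information between random contingency tables with the observed
#' margins (hypergeometric model). Used to compare two clusterings when
#' neither is ground truth; independent partitions score about 0.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return The AMI value (at most 1; can be slightly negative).
#' @export
ami <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must have equal length", call. = FALSE)
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  a <- rowSums(tab)
  b <- colSums(tab)
  hx <- entropy_nat(a / n)
  hy <- entropy_nat(b / n)
  p <- tab / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(a / n, b / n)[nz]))
  emi <- expected_mi(a, b, n)
  denom <- (hx + hy) / 2 - emi
  if (abs(denom) < .Machine$double.eps) {
    # both partitions trivial (single cluster or all singletons agree)
    return(if (mi - emi == 0) 1 else 0)
  }
  (mi - emi) / denom
}

# E[MI] under the permutation (hypergeometric) model, natural logs
expected_mi <- function(a, b, n) {
  emi <- 0
  lgn <- lgamma(n + 1)
  for (i in seq_along(a)) {
    ai <- a[i]
    for (j in seq_along(b)) {
      bj <- b[j]
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      nij <- lo:hi
      lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
        lgamma(n - bj + 1) - lgn - lgamma(nij + 1) - lgamma(ai - nij + 1) -
        lgamma(bj - nij + 1) - lgamma(pmax(n - ai - bj + nij, 0) + 1)
      term <- (nij / n) * log(nij * n / (ai * bj)) * exp(lp)
      emi <- emi + sum(term)
    }
  }
  emi
}
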