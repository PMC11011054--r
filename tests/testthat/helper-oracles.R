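# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct entropy sums,
# hand-rolled step-up correction.

# all set partitions of n items as restricted-growth label vectors
set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxb) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxb + 1L)) rec(c(prefix, b), max(maxb, b))
  }
  rec(integer(0), 0L)
  out
}

# all typed partitions of a graph: cartesian product of per-type set
# partitions, with disjoint label ranges across types
typed_partitions <- function(types) {
  utypes <- sort(unique(types))
  per_type <- lapply(utypes, function(t) set_partitions(sum(types == t)))
  grids <- do.call(expand.grid, lapply(per_type, seq_along))
  lapply(seq_len(nrow(grids)), function(i) {
    part <- integer(length(types))
    offset <- 0L
    for (j in seq_along(utypes)) {
      p <- per_type[[j]][[grids[i, j]]]
      part[types == utypes[j]] <- offset + p
      offset <- offset + max(p)
    }
    part
  })
}

# exhaustive min description length over all typed partitions
enumerate_min_dl <- function(graph) {
  types <- sctopics:::graph_type_codes(graph)
  parts <- typed_partitions(types)
  sigmas <- vapply(parts, function(p) description_length(graph, p), numeric(1))
  list(sigma = min(sigmas), partition = parts[[which.min(sigmas)]],
       n_partitions = length(parts))
}

# direct-entropy NMI (arithmetic-mean normalization), written independently
oracle_nmi <- function(a, b) {
  n <- length(a)
  ha <- 0; hb <- 0; mi <- 0
  for (x in unique(a)) {
    px <- sum(a == x) / n
    ha <- ha - px * log(px)
  }
  for (y in unique(b)) {
    py <- sum(b == y) / n
    hb <- hb - py * log(py)
  }
  if (ha == 0 || hb == 0) return(0)
  for (x in unique(a)) for (y in unique(b)) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0)
      mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  2 * mi / (ha + hb)
}

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  }
  out
}

# brute-force hypergeometric upper tail by enumeration over the support
oracle_hyper_tail <- function(N, K, n, k) {
  kk <- max(0, n + K - N):min(K, n)
  probs <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(probs[kk >= k])
}

# hand-rolled BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# reference implementation of the adaptive assignment loop: literal scan of
# the n grid, recomputing sets from scratch at every n
oracle_assign <- function(pc_mat, n_start = 3, step = 0.05) {
  # pc_mat: clusters x topics matrix
  grid <- seq(n_start, 0, by = -step)
  for (n in grid) {
    sets <- list()
    for (i in seq_len(nrow(pc_mat))) {
      x <- pc_mat[i, ]
      mu <- mean(x)
      sg <- sqrt(mean((x - mu)^2))
      sets[[i]] <- which(x > mu + n * sg)
    }
    if (any(lengths(sets) == 0)) next
    keys <- vapply(sets, paste, character(1), collapse = ",")
    if (anyDuplicated(keys) == 0) return(list(n = n, sets = sets))
  }
  NULL
}

# sklearn AMI through the system python, batched over label-pair lists
sklearn_ami <- function(pairs) {
  payload <- jsonlite::toJSON(pairs, auto_unbox = FALSE)
  script <- paste(
    "import sys, json",
    "from sklearn.metrics import adjusted_mutual_info_score as f",
    "pairs = json.load(sys.stdin)",
    "print(json.dumps([f(p[0], p[1]) for p in pairs]))",
    sep = "; ")
  out <- system2("python", c("-c", shQuote(script)), input = payload,
                 stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(out)
}

# small deterministic bipartite fixture graphs (<= 8 nodes) for exhaustive
# enumeration checks
tiny_fixture_graphs <- function() {
  mk <- function(mat, name) {
    build_graph(count_layer(mat,
                            genes = paste0("g", seq_len(nrow(mat))),
                            cells = paste0("c", seq_len(ncol(mat))),
                            layer_name = name))
  }
  list(
    diag3 = mk(diag(c(3, 3, 3)), "L"),
    two_vs_one = mk(rbind(c(4, 4, 0), c(0, 1, 3), c(1, 0, 4)), "L"),
    asym = mk(rbind(c(2, 0), c(1, 3), c(0, 2), c(3, 1)), "L"),
    hub = mk(rbind(c(5, 5, 5), c(1, 0, 0)), "L")
  )
}
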