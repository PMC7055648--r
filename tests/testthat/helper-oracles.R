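# Independent brute-force oracles. These deliberately share no code with the
# package's optimized implementations.

# All set partitions of n elements as restricted-growth label matrices
# (Bell(n) rows). Memoized: the n = 10 table (115,975 partitions) is reused
# across acceptance blocks.
.partition_cache <- new.env(parent = emptyenv())

all_set_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  res <- vector("list", 0)
  a <- integer(n)
  rec <- function(i, mx) {
    if (i > n) {
      res[[length(res) + 1L]] <<- a
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1L)) {
      a[i] <<- v
      rec(i + 1L, max(mx, v))
    }
  }
  rec(1L, 0L)
  out <- do.call(rbind, res)
  .partition_cache[[key]] <- out
  out
}

# Pair-coassignment indicator matrix: rows = partitions, cols = unordered
# node pairs (upper triangle, column-major). Q for every partition of a
# matrix B (zero diagonal) is IND %*% (2 * B[upper.tri]).
pair_indicator <- function(P) {
  key <- paste0("ind", ncol(P))
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  pairs <- which(upper.tri(diag(ncol(P))), arr.ind = TRUE)
  IND <- vapply(seq_len(nrow(pairs)), function(k)
    as.numeric(P[, pairs[k, 1]] == P[, pairs[k, 2]]), numeric(nrow(P)))
  .partition_cache[[key]] <- IND
  IND
}

# Exhaustive maximum of ordered-pair uniform-null modularity.
brute_force_max_q <- function(B) {
  stopifnot(isSymmetric(B))
  P <- all_set_partitions(nrow(B))
  IND <- pair_indicator(P)
  qs <- as.numeric(IND %*% (2 * B[upper.tri(B)]))
  list(qmax = max(qs), labels = P[which.max(qs), ])
}

# Naive double-loop evaluation of single-layer Q (ordered pairs).
naive_modularity <- function(W, labels, gamma) {
  n <- nrow(W)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && labels[i] == labels[j]) q <- q + W[i, j] - gamma
  }
  q
}

# Naive evaluation of multilayer Q: intra-layer ordered pairs plus
# categorical interlayer coupling over ordered layer pairs.
naive_multilayer_q <- function(layers, labels, gamma, omega) {
  T <- length(layers)
  n <- nrow(layers[[1]])
  q <- 0
  for (s in seq_len(T)) {
    W <- layers[[s]]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && labels[i, s] == labels[j, s]) q <- q + W[i, j] - gamma
    }
  }
  for (i in seq_len(n)) for (s in seq_len(T)) for (r in seq_len(T)) {
    if (s != r && labels[i, s] == labels[i, r]) q <- q + omega
  }
  q
}

# Monte-Carlo standard deviation of the coassigned-in-both pair count under
# random relabeling (permutation null of the z-Rand index).
perm_sd_w <- function(x, y, n_perm = 5000) {
  stats::sd(replicate(n_perm, {
    yp <- sample(y)
    nij <- table(x, yp)
    sum(nij * (nij - 1)) / 2
  }))
}

canon_labels <- function(l) match(l, unique(l))

derive_seeds_for_test <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

rand_signed_matrix <- function(n, lim = 1) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- stats::runif(n * (n - 1) / 2, -lim, lim)
  W + t(W)
}
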