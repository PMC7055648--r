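#' Signed modularity with a uniform null model
#'
#' Evaluates `Q = sum_{i != j, g_i = g_j} (A_ij - gamma)`, the modularity of a
#' partition under the uniform null `P_ij = 1` appropriate for correlation
#' matrices. The sum runs over ordered pairs (each unordered pair counted
#' twice) and excludes self-pairs, so the all-singletons partition scores
#' exactly zero.
#'
#' @param A An [fc_network()] or symmetric weight matrix (zero diagonal).
#' @param partition Integer vector of module labels covering all nodes, or a
#'   `partition` object.
#' @param gamma Resolution parameter.
#' @return Scalar modularity Q.
#' @export
modularity_score <- function(A, partition, gamma) {
  W <- fc_weights(A)
  labels <- partition_labels(partition, nrow(W))
  q <- 0
  for (m in unique(labels)) {
    idx <- which(labels == m)
    nm <- length(idx)
    if (nm > 1L) {
      block <- W[idx, idx, drop = FALSE]
      q <- q + sum(block) - sum(diag(block)) - gamma * nm * (nm - 1)
    }
  }
  q
}

partition_labels <- function(partition, n) {
  labels <- if (inherits(partition, "partition")) partition$labels
  else as.integer(partition)
  if (length(labels) != n || anyNA(labels))
    stop_mesoconn("partition must label all ", n, " nodes",
                  class = "invalid_partition")
  labels
}

new_partition <- function(labels, q = NA_real_, gamma = NA_real_) {
  labels <- canonicalize_labels(labels)
  base::structure(
    list(labels = labels, n_modules = max(labels), q = q, gamma = gamma),
    class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d nodes in %d modules (Q = %.4g, gamma = %.4g)\n",
              length(x$labels), x$n_modules, x$q, x$gamma))
  invisible(x)
}

# Randomized-order single-node move sweeps on a modularity matrix M
# (diagonal ignored: self-loop weight travels with the node). `comm` is the
# starting assignment; labels index into 1..length(comm)+ so an isolated
# fresh community can reuse any empty label. Moves use unordered-pair gains;
# the ordered-pair Q of the quality function is exactly twice that, so
# argmax partitions coincide. Consumes the current RNG stream.
sweep_moves <- function(M, comm, tol = 1e-12) {
  m <- nrow(M)
  size <- tabulate(comm, nbins = m)
  repeat {
    improved <- FALSE
    for (i in sample.int(m)) {
      ci <- comm[i]
      w <- M[, i]
      w[i] <- 0
      agg <- rowsum(w, comm, reorder = FALSE)
      cs <- numeric(m)
      cs[as.integer(rownames(agg))] <- agg
      leave <- cs[ci]                # links to own community (w[i] = 0)
      cs[ci] <- -Inf                 # staying is not a move
      best <- which.max(cs)
      best_gain <- max(cs[best], 0)  # 0 = gain of a fresh singleton
      if (best_gain - leave > tol) {
        if (cs[best] >= 0) {
          target <- best
        } else {
          # isolation beats every existing community
          empty <- which(size == 0L)
          if (!length(empty)) next
          target <- empty[1L]
        }
        size[ci] <- size[ci] - 1L
        size[target] <- size[target] + 1L
        comm[i] <- target
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  comm
}

aggregate_matrix <- function(M, comm) {
  rowsum(t(rowsum(M, comm, reorder = TRUE)), comm, reorder = TRUE)
}

# Classic multilevel phase: sweeps from singletons, aggregate, repeat.
louvain_multilevel <- function(M, tol = 1e-12) {
  membership <- seq_len(nrow(M))
  repeat {
    m <- nrow(M)
    comm <- canonicalize_labels(sweep_moves(M, seq_len(m), tol))
    membership <- comm[membership]
    if (max(comm) == m) break
    M <- aggregate_matrix(M, comm)
  }
  membership
}

# One Louvain run with flat refinement: after the multilevel phase, node
# moves are re-attempted on the original (unaggregated) matrix and the
# multilevel phase re-run on the re-aggregated matrix, until stable. The
# refinement escapes local optima created by premature aggregation.
louvain_once <- function(B, tol = 1e-12, init = NULL) {
  labels <- if (is.null(init)) canonicalize_labels(louvain_multilevel(B, tol))
  else canonicalize_labels(init)
  repeat {
    comm <- canonicalize_labels(sweep_moves(B, labels, tol))
    if (identical(comm, labels) || max(comm) == 1L) return(comm)
    if (max(comm) < nrow(B)) {
      sub <- louvain_multilevel(aggregate_matrix(B, comm), tol)
      comm2 <- canonicalize_labels(sub[comm])
    } else comm2 <- comm
    if (identical(comm2, labels)) return(comm2)
    labels <- comm2
  }
}

#' Maximize signed uniform-null modularity with the Louvain heuristic
#'
#' Greedy node-move sweeps in randomized order followed by module
#' aggregation, repeated until no move increases Q, on the modularity matrix
#' `B = A - gamma` (off-diagonal). Runs `n_restarts` independent restarts and
#' returns the best partition found.
#'
#' @param A An [fc_network()] or symmetric weight matrix.
#' @param gamma Resolution parameter.
#' @param seed Integer seed (restart `k` derives its own sub-seed).
#' @param n_restarts Number of random restarts.
#' @return A `partition` (fields `labels`, `n_modules`, `q`, `gamma`).
#' @export
louvain_optimize <- function(A, gamma, seed = 1L, n_restarts = 10L) {
  W <- fc_weights(A)
  if (any(!is.finite(W)))
    stop_mesoconn("weights must be finite", class = "invalid_network")
  B <- W - gamma
  diag(B) <- 0
  seeds <- derive_seeds(seed, n_restarts)
  n <- nrow(B)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    labels <- with_seed(seeds[[r]], {
      # first restart starts from singletons; later restarts from random
      # partitions, which diversifies the local optima reached
      init <- if (r == 1L) NULL else
        sample.int(sample.int(max(n - 1L, 1L), 1L) + 1L, n, replace = TRUE)
      louvain_once(B, init = init)
    })
    q <- modularity_score(W, labels, gamma)
    if (is.null(best) || q > best$q + 1e-12)
      best <- list(labels = labels, q = q)
  }
  new_partition(best$labels, q = best$q, gamma = gamma)
}

#' Resolution-parameter bounds enclosing all non-trivial partitions
#'
#' `gamma_max` is the maximum off-diagonal weight: above it every modularity
#' matrix entry is negative and the optimal partition is all singletons.
#' `gamma_min` is the smallest resolution at which optimization first yields
#' two or more modules, located by bisection (repeated Louvain runs) between
#' the minimum off-diagonal weight and `gamma_max`.
#'
#' @param A An [fc_network()] or symmetric weight matrix (N >= 2).
#' @param seed Integer seed for the bisection's Louvain runs.
#' @param n_iter Bisection iterations.
#' @return Numeric `c(gamma_min, gamma_max)`.
#' @export
gamma_bounds <- function(A, seed = 1L, n_iter = 25L) {
  W <- fc_weights(A)
  off <- W[row(W) != col(W)]
  if (length(off) == 0L || diff(range(off)) == 0)
    stop_mesoconn("degenerate weight matrix: all off-diagonal weights equal",
                  class = "degenerate_bounds")
  gamma_max <- max(off)
  lo <- min(off)       # all B >= 0: one module
  hi <- gamma_max
  seeds <- derive_seeds(seed, n_iter)
  for (it in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    p <- louvain_optimize(W, mid, seed = seeds[[it]], n_restarts = 3L)
    if (p$n_modules >= 2L) hi <- mid else lo <- mid
  }
  c(gamma_min = hi, gamma_max = gamma_max)
}

#' Sample resolution parameters from the network's weight distribution
#'
#' Draws `n` values with replacement from the set of off-diagonal connection
#' weights falling inside `bounds`, so the resolution sweep mirrors the
#' empirical weight distribution.
#'
#' @param A An [fc_network()] or symmetric weight matrix.
#' @param n Number of samples.
#' @param bounds `c(gamma_min, gamma_max)` (see [gamma_bounds()]).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_gamma_values <- function(A, n, bounds, seed = 1L) {
  W <- fc_weights(A)
  off <- W[row(W) != col(W)]
  admissible <- off[off >= bounds[[1]] & off <= bounds[[2]]]
  if (length(admissible) == 0L)
    stop_mesoconn("no connection weights inside bounds",
                  class = "sampling_error")
  with_seed(seed, sample(admissible, n, replace = TRUE))
}

#' Build a module coassignment matrix from a partition ensemble
#'
#' Entry `(i, j)` is the fraction of partitions in which nodes `i` and `j`
#' share a module label.
#'
#' @param partitions List of `partition` objects or label vectors over a
#'   common node set.
#' @return An N x N symmetric matrix with unit diagonal, with the ensemble
#'   size in attribute `"n_partitions"`.
#' @export
build_coassignment <- function(partitions) {
  if (length(partitions) < 1L)
    stop_mesoconn("need at least one partition", class = "invalid_argument")
  labs <- lapply(partitions, function(p)
    if (inherits(p, "partition")) p$labels else as.integer(p))
  n <- length(labs[[1]])
  if (any(vapply(labs, length, 1L) != n))
    stop_mesoconn("partitions disagree on node count",
                  class = "invalid_argument")
  C <- coassign_from_matrix(do.call(rbind, labs))
  attr(C, "n_partitions") <- length(labs)
  C
}

# Coassignment from an ensemble x nodes label matrix via one sparse
# indicator cross-product: column block p of Z holds partition p's module
# indicators (one column per (partition, label) combination).
coassign_from_matrix <- function(P) {
  np <- nrow(P)
  n <- ncol(P)
  maxlab <- max(P)
  i_idx <- rep(seq_len(n), times = np)
  j_idx <- (rep(seq_len(np), each = n) - 1L) * maxlab + as.vector(t(P))
  Z <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = 1,
                            dims = c(n, np * maxlab))
  as.matrix(Matrix::tcrossprod(Z)) / np
}

# Expected coassignment of a node subset under independent uniform
# relabeling of each partition (preserving its module sizes within the
# subset): mean over partitions of sum n_k (n_k - 1) / (S (S - 1)).
expected_coassignment <- function(labs_sub) {
  S <- length(labs_sub[[1]])
  if (S < 2L) return(0)
  mean(vapply(labs_sub, function(l) {
    nk <- tabulate(canonicalize_labels(l))
    sum(nk * (nk - 1)) / (S * (S - 1))
  }, 1))
}

#' Hierarchical consensus clustering of a partition ensemble
#'
#' Summarizes an ensemble of partitions (for example, one Louvain partition
#' per sampled resolution) as a coassignment matrix and recursively splits
#' it: at each node set, the coassignment submatrix minus its
#' permutation-null expectation is clustered with Louvain; a candidate split
#' is accepted only if its consensus modularity exceeds the distribution
#' obtained by independently permuting each ensemble partition's labels
#' within the node set (`n_perm` permutations, level `alpha`). Accepted
#' splits recurse, yielding nested partitions from coarse to fine.
#'
#' @param partitions List of `partition` objects or label vectors.
#' @param alpha Significance level for accepting a split.
#' @param seed Integer seed.
#' @param n_perm Permutations per split test.
#' @param min_size Smallest node set considered for further splitting
#'   (smaller sets become leaves without testing).
#' @param A Optional [fc_network()] used to attach a modularity value per
#'   hierarchy level.
#' @param gammas Optional vector of the resolution parameter used for each
#'   ensemble partition (provenance; also used to pick a representative
#'   resolution per level).
#' @return A `hierarchy`: list with `levels` (list of `partition`, coarse to
#'   fine, each refining its parent), `gamma_per_level`, `q_per_level`,
#'   `alpha`, `n_partitions`.
#' @export
consensus_hierarchy <- function(partitions, alpha = 0.05, seed = 1L,
                                n_perm = 100L, min_size = 4L, A = NULL,
                                gammas = NULL) {
  labs <- lapply(partitions, function(p)
    if (inherits(p, "partition")) p$labels else as.integer(p))
  n <- length(labs[[1]])
  P <- do.call(rbind, labs)                 # ensemble x nodes
  seeds <- derive_seeds(seed, 2L)
  rng_split <- seeds[[1]]
  rng_perm <- seeds[[2]]
  split_counter <- 0L

  try_split <- function(nodes) {
    S <- length(nodes)
    if (S < max(2L, min_size)) return(NULL)
    Psub <- P[, nodes, drop = FALSE]
    Csub <- coassign_from_matrix(Psub)
    labs_sub <- lapply(seq_len(nrow(Psub)), function(k) Psub[k, ])
    mu <- expected_coassignment(labs_sub)   # invariant under permutation
    Bcons <- Csub - mu
    diag(Bcons) <- 0
    split_counter <<- split_counter + 1L
    part <- louvain_optimize(Bcons, gamma = 0,
                             seed = rng_split + split_counter,
                             n_restarts = 5L)
    if (part$n_modules < 2L) return(NULL)
    q_obs <- part$q
    # Null: permute each ensemble partition's labels within the node set.
    # Sequential early rejection: once enough null draws reach q_obs that
    # p >= alpha is guaranteed, stop permuting.
    reject_at <- ceiling(alpha * (1 + n_perm))
    exceed <- with_seed(rng_perm + split_counter, {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        Pp <- Psub
        for (k in seq_len(nrow(Pp))) Pp[k, ] <- Pp[k, sample.int(S)]
        Bp <- coassign_from_matrix(Pp) - mu
        diag(Bp) <- 0
        q_b <- modularity_score(Bp, louvain_once(Bp), 0)
        if (q_b >= q_obs) {
          cnt <- cnt + 1L
          if (cnt >= reject_at) break
        }
      }
      cnt
    })
    p <- (1 + exceed) / (1 + n_perm)
    if (p >= alpha) return(NULL)
    split(nodes, part$labels)
  }

  # Breadth-first recursion: each round refines every current group that
  # admits a significant split; rounds become hierarchy levels.
  current <- list(seq_len(n))
  levels <- list()
  repeat {
    nxt <- list()
    any_split <- FALSE
    for (grp in current) {
      children <- try_split(grp)
      if (is.null(children)) {
        nxt <- c(nxt, list(grp))
      } else {
        nxt <- c(nxt, unname(children))
        any_split <- TRUE
      }
    }
    if (!any_split) break
    labels <- integer(n)
    for (k in seq_along(nxt)) labels[nxt[[k]]] <- k
    levels <- c(levels, list(new_partition(labels)))
    current <- nxt
  }
  if (length(levels) == 0L)
    levels <- list(new_partition(rep(1L, n)))

  gamma_per_level <- rep(NA_real_, length(levels))
  q_per_level <- rep(NA_real_, length(levels))
  if (!is.null(gammas)) {
    counts <- vapply(labs, function(l) length(unique(l)), 1L)
    for (k in seq_along(levels)) {
      target <- levels[[k]]$n_modules
      d <- abs(counts - target)
      gamma_per_level[k] <- stats::median(gammas[d == min(d)])
    }
  }
  if (!is.null(A)) {
    for (k in seq_along(levels)) {
      g <- if (is.finite(gamma_per_level[k])) gamma_per_level[k] else
        mean(fc_weights(A)[upper.tri(fc_weights(A))])
      q_per_level[k] <- modularity_score(A, levels[[k]], g)
      levels[[k]]$q <- q_per_level[k]
      levels[[k]]$gamma <- g
    }
  }
  base::structure(
    list(levels = levels, gamma_per_level = gamma_per_level,
         q_per_level = q_per_level, alpha = alpha,
         n_partitions = length(labs)),
    class = "hierarchy")
}

#' @export
print.hierarchy <- function(x, ...) {
  cat(sprintf("hierarchy: %d levels (modules: %s)\n", length(x$levels),
              paste(vapply(x$levels, `[[`, 1L, "n_modules"),
                    collapse = " -> ")))
  invisible(x)
}

#' Surrogate-based significance of modularity per hierarchy level
#'
#' For each hierarchy level, compares the empirical maximized Q (Louvain on
#' the observed network at the level's representative resolution) against
#' the distribution of maximized Q over networks built from phase-randomized
#' surrogate time series at the same resolution. The permutation p-value is
#' `(1 + #{Q_surr >= Q_emp}) / (1 + n_surrogates)`, Bonferroni-corrected
#' across levels.
#'
#' @param A An [fc_network()] (or matrix): the empirical network.
#' @param surrogate_fcs List of surrogate [fc_network()]s or matrices.
#' @param gammas Resolution parameter per level (e.g.
#'   `hierarchy$gamma_per_level`).
#' @param seed Integer seed for the Louvain runs.
#' @param n_restarts Louvain restarts per optimization.
#' @return Data frame with one row per level: `gamma`, `q_emp`, `p`,
#'   `p_bonferroni`.
#' @export
modularity_significance <- function(A, surrogate_fcs, gammas, seed = 1L,
                                    n_restarts = 3L) {
  n_surr <- length(surrogate_fcs)
  if (n_surr < 20L)
    warning("fewer than 20 surrogates: p-value resolution is coarse")
  L <- length(gammas)
  seeds <- derive_seeds(seed, L * (1L + n_surr))
  k <- 1L
  rows <- lapply(seq_len(L), function(l) {
    g <- gammas[[l]]
    q_emp <- louvain_optimize(A, g, seed = seeds[[k]],
                              n_restarts = n_restarts)$q
    k <<- k + 1L
    q_surr <- vapply(surrogate_fcs, function(s) {
      q <- louvain_optimize(s, g, seed = seeds[[k]],
                            n_restarts = n_restarts)$q
      k <<- k + 1L
      q
    }, 1)
    p <- (1 + sum(q_surr >= q_emp)) / (1 + n_surr)
    data.frame(level = l, gamma = g, q_emp = q_emp, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * L)
  out
}
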