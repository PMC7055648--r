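#' Assemble a multilayer network from per-condition FC layers
#'
#' Layers are condition-specific functional networks over the same node set;
#' every node is coupled to itself in all other layers (categorical
#' all-to-all coupling) with weight `omega`.
#'
#' @param layers List of [fc_network()]s or symmetric matrices sharing N.
#' @param omega Interlayer coupling weight (>= 0).
#' @param layer_labels Optional condition names (defaults to list names).
#' @return An object of class `multilayer_network` with fields `layers`
#'   (weight matrices), `omega`, `layer_labels`, `n_nodes`, `n_layers`.
#' @export
multilayer_network <- function(layers, omega, layer_labels = NULL) {
  if (length(layers) < 2L)
    stop_mesoconn("need at least 2 layers", class = "invalid_argument")
  if (omega < 0)
    stop_mesoconn("omega must be >= 0", class = "invalid_argument")
  mats <- lapply(layers, fc_weights)
  ns <- vapply(mats, nrow, 1L)
  if (length(unique(ns)) != 1L)
    stop_mesoconn("layers differ in node count",
                  class = "incompatible_networks")
  labels <- layer_labels %||% names(layers) %||%
    sprintf("layer%d", seq_along(layers))
  base::structure(
    list(layers = mats, omega = omega, layer_labels = labels,
         n_nodes = ns[[1]], n_layers = length(mats)),
    class = "multilayer_network")
}

# Supra-modularity matrix: intra-layer diagonal blocks B_s = A_s - gamma
# (zero diagonal), interlayer entries omega between copies of the same node.
supra_modularity_matrix <- function(net, gamma) {
  N <- net$n_nodes; T <- net$n_layers
  S <- matrix(0, N * T, N * T)
  for (s in seq_len(T)) {
    idx <- (s - 1L) * N + seq_len(N)
    B <- net$layers[[s]] - gamma
    diag(B) <- 0
    S[idx, idx] <- B
  }
  if (net$omega != 0) {
    for (s in seq_len(T)) for (r in seq_len(T)) {
      if (s == r) next
      S[cbind((s - 1L) * N + seq_len(N), (r - 1L) * N + seq_len(N))] <-
        net$omega
    }
  }
  S
}

multilayer_labels <- function(partition, N, T) {
  labels <- if (inherits(partition, "multilayer_partition"))
    partition$labels else as.matrix(partition)
  if (!is.matrix(labels) || nrow(labels) != N || ncol(labels) != T ||
      anyNA(labels))
    stop_mesoconn("partition must be a complete N x T label matrix",
                  class = "invalid_partition")
  labels
}

new_multilayer_partition <- function(labels, q = NA_real_,
                                     gamma = NA_real_, omega = NA_real_,
                                     layer_labels = NULL) {
  labels <- matrix(canonicalize_labels(as.vector(labels)),
                   nrow(labels), ncol(labels))
  if (!is.null(layer_labels)) colnames(labels) <- layer_labels
  n_per_layer <- apply(labels, 2, function(l) length(unique(l)))
  base::structure(
    list(labels = labels, n_modules = max(labels),
         n_modules_mean = mean(n_per_layer), q = q, gamma = gamma,
         omega = omega),
    class = "multilayer_partition")
}

#' @export
print.multilayer_partition <- function(x, ...) {
  cat(sprintf(
    "multilayer_partition: %d nodes x %d layers, %d modules (mean %.2f/layer)\n",
    nrow(x$labels), ncol(x$labels), x$n_modules, x$n_modules_mean))
  invisible(x)
}

#' Multilayer signed modularity with uniform null
#'
#' `Q = sum_s sum_{i != j} (A_s,ij - gamma) d(g_is, g_js)
#'    + omega * sum_i sum_{s != r} d(g_is, g_ir)`
#' — the intra-layer uniform-null modularity of every layer plus the
#' categorical interlayer coupling term, both over ordered pairs.
#'
#' @param net A [multilayer_network()].
#' @param partition N x T label matrix or `multilayer_partition`.
#' @param gamma Resolution parameter.
#' @return Scalar multilayer Q.
#' @export
multilayer_modularity_score <- function(net, partition, gamma) {
  labels <- multilayer_labels(partition, net$n_nodes, net$n_layers)
  q <- 0
  for (s in seq_len(net$n_layers))
    q <- q + modularity_score(net$layers[[s]], labels[, s], gamma)
  if (net$omega != 0) {
    same <- apply(labels, 1, function(g) {
      tab <- tabulate(canonicalize_labels(g))
      sum(tab * (tab - 1))
    })
    q <- q + net$omega * sum(same)
  }
  q
}

#' Louvain optimization of multilayer modularity
#'
#' Runs the Louvain heuristic on the supra-modularity matrix (N*T nodes:
#' layer-wise blocks `A_s - gamma`, interlayer coupling `omega` between
#' copies of a node), so modules are detected in all layers simultaneously
#' and module labels are shared across layers.
#'
#' @param net A [multilayer_network()].
#' @param gamma Resolution parameter.
#' @param seed Integer seed.
#' @param n_restarts Random restarts; the best-Q labeling is returned.
#' @param n_perturb Iterated-local-search cycles after the restarts: a
#'   random fifth of the supra-nodes is reassigned and the heuristic rerun,
#'   keeping improvements (escapes coordinated multi-node local optima).
#' @return A `multilayer_partition` (fields `labels` N x T, `n_modules`,
#'   `n_modules_mean`, `q`, `gamma`, `omega`).
#' @export
multilayer_louvain <- function(net, gamma, seed = 1L, n_restarts = 10L,
                               n_perturb = 10L) {
  stopifnot(inherits(net, "multilayer_network"))
  S <- supra_modularity_matrix(net, gamma)
  if (any(!is.finite(S)))
    stop_mesoconn("weights must be finite", class = "invalid_network")
  seeds <- derive_seeds(seed, n_restarts)
  nt <- nrow(S)
  # layer-aligned warm start: single-layer solution of the mean layer,
  # replicated across layers (the coupling-dominated optimum's shape)
  mean_layer <- Reduce(`+`, net$layers) / net$n_layers
  aligned <- rep(with_seed(seeds[[1L]],
                           louvain_once({
                             B <- mean_layer - gamma
                             diag(B) <- 0
                             B
                           })), net$n_layers)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    flat <- with_seed(seeds[[r]], {
      init <- if (r == 1L) NULL
      else if (r == 2L) aligned
      else sample.int(sample.int(max(nt - 1L, 1L), 1L) + 1L, nt,
                      replace = TRUE)
      louvain_once(S, init = init)
    })
    labels <- matrix(flat, net$n_nodes, net$n_layers)
    q <- multilayer_modularity_score(net, labels, gamma)
    if (is.null(best) || q > best$q + 1e-12)
      best <- list(labels = labels, q = q, flat = flat)
  }
  if (n_perturb > 0L) {
    pseeds <- derive_seeds(seed + 1L, n_perturb)
    for (r in seq_len(n_perturb)) {
      flat <- with_seed(pseeds[[r]], {
        init <- best$flat
        kick <- sample.int(nt, max(2L, round(nt / 5)))
        init[kick] <- sample.int(max(init) + 1L, length(kick),
                                 replace = TRUE)
        louvain_once(S, init = init)
      })
      labels <- matrix(flat, net$n_nodes, net$n_layers)
      q <- multilayer_modularity_score(net, labels, gamma)
      if (q > best$q + 1e-12)
        best <- list(labels = labels, q = q, flat = flat)
    }
  }
  new_multilayer_partition(best$labels, q = best$q, gamma = gamma,
                           omega = net$omega,
                           layer_labels = net$layer_labels)
}

#' Sample interlayer coupling values from a log-uniform distribution
#'
#' Draws exponents uniformly on `exponent_range` and returns `10^u`, so with
#' the default range the smallest and largest possible values are 0.001 and
#' 10.
#'
#' @param n Number of samples (>= 1).
#' @param exponent_range `c(lo, hi)` for the base-10 exponent.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_omega_values <- function(n, exponent_range = c(-3, 1), seed = 1L) {
  if (n < 1) stop_mesoconn("n must be >= 1", class = "invalid_argument")
  if (exponent_range[[1]] > exponent_range[[2]])
    stop_mesoconn("inverted exponent_range", class = "invalid_argument")
  with_seed(seed, 10^stats::runif(n, exponent_range[[1]],
                                  exponent_range[[2]]))
}

#' Node flexibility of a multilayer partition
#'
#' `f_i = 1 - 2/(T(T-1)) * sum_{r < s} d(g_ir, g_is)`: the fraction of layer
#' pairs in which node `i`'s module assignment differs. 0 means the node
#' keeps one module in every layer; 1 means it never repeats a module.
#'
#' @param partition A `multilayer_partition` or N x T label matrix (T >= 2).
#' @return A `flexibility_profile`: list with `f` (per-node, in `[0, 1]`),
#'   `n_layers`, and `mean_modules` (mean modules per layer, used for
#'   filtering in [flexibility_summary()]).
#' @export
compute_flexibility <- function(partition) {
  labels <- if (inherits(partition, "multilayer_partition"))
    partition$labels else as.matrix(partition)
  T <- ncol(labels)
  if (T < 2L)
    stop_mesoconn("flexibility needs at least 2 layers",
                  class = "undefined_flexibility")
  agree <- apply(labels, 1, function(g) {
    tab <- tabulate(canonicalize_labels(g))
    sum(tab * (tab - 1)) / 2
  })
  f <- 1 - 2 * agree / (T * (T - 1))
  mean_modules <- if (inherits(partition, "multilayer_partition"))
    partition$n_modules_mean else
      mean(apply(labels, 2, function(l) length(unique(l))))
  base::structure(
    list(f = f, n_layers = T, mean_modules = mean_modules),
    class = "flexibility_profile")
}

#' Average node flexibility over an ensemble of multilayer partitions
#'
#' Averages per-node flexibility over profiles whose mean module count per
#' layer lies inside `module_range` (profiles outside the range — near-trivial
#' one-module or near-singleton solutions — are discarded). Also returns the
#' rank-transformed mean, which removes baseline flexibility differences
#' across coupling strengths.
#'
#' @param profiles List of `flexibility_profile`s (see
#'   [compute_flexibility()]).
#' @param module_range `c(lo, hi)` bounds on mean modules per layer.
#' @return List with `f_mean` (per node), `f_rank` (ranks of `f_mean`),
#'   `n_used`.
#' @export
flexibility_summary <- function(profiles, module_range = c(2, 25)) {
  keep <- vapply(profiles, function(p)
    p$mean_modules >= module_range[[1]] &&
      p$mean_modules <= module_range[[2]], TRUE)
  if (!any(keep))
    stop_mesoconn("no profiles with mean module count in [",
                  module_range[[1]], ", ", module_range[[2]], "]",
                  class = "empty_summary")
  fs <- vapply(profiles[keep], `[[`, numeric(length(profiles[[1]]$f)), "f")
  fs <- matrix(fs, ncol = sum(keep))
  f_mean <- rowMeans(fs)
  list(f_mean = f_mean, f_rank = rank(f_mean), n_used = sum(keep))
}

#' Run a multilayer ensemble over sampled (gamma, omega) pairs
#'
#' One Louvain optimization per paired (gamma, omega) draw, as in resolution
#' sampling for single-layer hierarchies; returns the flexibility profiles
#' and partitions for downstream summaries.
#'
#' @param layers List of per-condition [fc_network()]s or matrices.
#' @param gammas,omegas Equal-length numeric vectors of sampled parameters.
#' @param seed Integer seed.
#' @param n_restarts Louvain restarts per run (1 mirrors one run per draw).
#' @param n_perturb Iterated-local-search cycles per run (kept small: the
#'   ensemble averages over draws, so per-run polish matters little).
#' @return List with `partitions`, `profiles`, `gammas`, `omegas`.
#' @export
multilayer_ensemble <- function(layers, gammas, omegas, seed = 1L,
                                n_restarts = 1L, n_perturb = 2L) {
  stopifnot(length(gammas) == length(omegas))
  seeds <- derive_seeds(seed, length(gammas))
  partitions <- vector("list", length(gammas))
  profiles <- vector("list", length(gammas))
  for (k in seq_along(gammas)) {
    net <- multilayer_network(layers, omega = omegas[[k]])
    partitions[[k]] <- multilayer_louvain(net, gammas[[k]],
                                          seed = seeds[[k]],
                                          n_restarts = n_restarts,
                                          n_perturb = n_perturb)
    profiles[[k]] <- compute_flexibility(partitions[[k]])
  }
  list(partitions = partitions, profiles = profiles, gammas = gammas,
       omegas = omegas)
}
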