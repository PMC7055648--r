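#' Participation coefficient over positive connections
#'
#' `p_i = 1 - sum_c (kappa_ic / k_i)^2`, where `kappa_ic` is node `i`'s total
#' positive weight to module `c` and `k_i` its total positive strength. Near
#' 1: connections spread uniformly over modules (connector hub); near 0:
#' concentrated in few modules. Nodes with zero positive strength get 0 by
#' convention.
#'
#' @param A An [fc_network()] or symmetric weight matrix.
#' @param partition Module labels or `partition` object.
#' @return Per-node participation in `[0, 1]`.
#' @export
participation_coefficient <- function(A, partition) {
  W <- fc_weights(A)
  labels <- partition_labels(partition, nrow(W))
  Wp <- pmax(W, 0)
  diag(Wp) <- 0
  Z <- outer(labels, sort(unique(labels)), "==") * 1
  kappa <- Wp %*% Z
  k <- rowSums(Wp)
  p <- 1 - rowSums((kappa / ifelse(k > 0, k, 1))^2)
  p[k == 0] <- 0
  as.numeric(p)
}

#' Participation across a module hierarchy
#'
#' Computes each node's participation coefficient at every hierarchy level,
#' the per-node mean over levels, its rank transform, and the cross-level
#' correlation matrix of participation maps.
#'
#' @param A An [fc_network()] or symmetric weight matrix.
#' @param hierarchy A `hierarchy` (see [consensus_hierarchy()]) or list of
#'   partitions.
#' @return List with `per_level` (N x L matrix), `mean`, `rank`,
#'   `level_correlation` (L x L), `strength` (per-node absolute strength).
#' @export
hierarchy_participation <- function(A, hierarchy) {
  levels <- if (inherits(hierarchy, "hierarchy")) hierarchy$levels
  else hierarchy
  if (length(levels) == 0L)
    stop_mesoconn("empty hierarchy", class = "invalid_argument")
  W <- fc_weights(A)
  per_level <- vapply(levels, function(p)
    participation_coefficient(W, p), numeric(nrow(W)))
  per_level <- matrix(per_level, nrow = nrow(W))
  p_mean <- rowMeans(per_level)
  level_cor <- if (ncol(per_level) > 1L) {
    suppressWarnings(stats::cor(per_level))
  } else matrix(1, 1, 1)
  list(per_level = per_level, mean = p_mean, rank = rank(p_mean),
       level_correlation = level_cor, strength = absolute_strength(W))
}

#' Absolute strength of each node
#'
#' `s_i = sum_j |A_ij|`: the total magnitude of a node's connection weights,
#' positive and negative alike.
#'
#' @param A An [fc_network()] or symmetric weight matrix.
#' @return Per-node nonnegative strength.
#' @export
absolute_strength <- function(A) {
  W <- fc_weights(A)
  diag(W) <- 0
  rowSums(abs(W))
}

#' z-score of the Rand index between two partitions
#'
#' Standardizes the count of node pairs coassigned in both partitions
#' against its mean and variance under uniform random relabeling, correcting
#' the Rand index for the number and size of modules:
#' `Z_r = (w_XY - W_X W_Y / W) / sigma_wXY`, with the closed-form variance of
#' Traud, Kelsic, Mucha & Porter. Pair counts use exact arithmetic on
#' doubles (safe for N <= 1e4).
#'
#' @param X,Y Partitions (label vectors or `partition` objects) over the
#'   same N >= 3 nodes; neither may be all-singletons or single-module
#'   (variance is zero there).
#' @return List with `z`, the one-sided p-value `p` (normal upper tail), and
#'   `components` (`W`, `W_X`, `W_Y`, `w_XY`, `sigma_wXY`).
#' @export
zrand_score <- function(X, Y) {
  x <- canonicalize_labels(if (inherits(X, "partition")) X$labels else X)
  y <- canonicalize_labels(if (inherits(Y, "partition")) Y$labels else Y)
  n <- length(x)
  if (length(y) != n || n < 3)
    stop_mesoconn("partitions must share N >= 3 nodes",
                  class = "invalid_argument")
  nij <- table(x, y)
  ni <- rowSums(nij)
  nj <- colSums(nij)
  M <- n * (n - 1) / 2
  M1 <- sum(ni * (ni - 1)) / 2
  M2 <- sum(nj * (nj - 1)) / 2
  w <- sum(nij * (nij - 1)) / 2
  if (M1 == 0 || M1 == M || M2 == 0 || M2 == M)
    stop_mesoconn("degenerate partition: variance of w is undefined",
                  class = "undefined_variance")
  C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * sum(ni^3)
  C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * sum(nj^3)
  a1 <- 4 * M1 - 2 * M
  a2 <- 4 * M2 - 2 * M
  var_w <- M / 16 -
    a1^2 * a2^2 / (256 * M^2) +
    C1 * C2 / (16 * n * (n - 1) * (n - 2)) +
    (a1^2 - 4 * C1 - 4 * M) * (a2^2 - 4 * C2 - 4 * M) /
      (64 * n * (n - 1) * (n - 2) * (n - 3))
  sigma <- sqrt(var_w)
  z <- (w - M1 * M2 / M) / sigma
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE),
       components = list(W = M, W_X = M1, W_Y = M2, w_XY = w,
                         sigma_wXY = sigma))
}

#' Geometric profile of connection weights
#'
#' Bins node pairs by Euclidean centroid distance and reports the mean
#' weight per bin (split into within- and between-hemisphere pairs when
#' hemisphere labels are supplied) together with the per-bin proportions of
#' four connection classes: anticorrelation (`w < -t_neutral`), neutral
#' (`|w| <= t_neutral`), weak positive (`t_neutral < w <= t_strong`), strong
#' positive (`w > t_strong`). Empty bins are reported as `NA`, not 0.
#'
#' @param A An [fc_network()] with coordinates (or matrix + `coords`).
#' @param bin_edges Distance bin edges (pixels); defaults to 10 equal-width
#'   bins covering the observed distances.
#' @param class_thresholds `c(t_neutral, t_strong)` in weight units.
#' @param coords Node coordinates if `A` is a bare matrix.
#' @param hemisphere Optional per-node `"L"`/`"R"` labels.
#' @return A `geometry_profile`: list with `bin_edges`, `bin_mid`,
#'   `mean_weight`, `mean_abs_weight`, optional `mean_weight_within` /
#'   `mean_weight_between`, `class_proportions` (4 x bins), `n_pairs`,
#'   `class_thresholds`.
#' @export
distance_profile <- function(A, bin_edges = NULL,
                             class_thresholds = c(0.1, 0.5),
                             coords = NULL, hemisphere = NULL) {
  W <- fc_weights(A)
  if (is.null(coords) && inherits(A, "fc_network")) coords <- A$coords
  if (is.null(coords))
    stop_mesoconn("node coordinates required", class = "invalid_argument")
  D <- as.matrix(stats::dist(coords))
  up <- upper.tri(W)
  d <- D[up]
  w <- W[up]
  if (is.null(bin_edges))
    bin_edges <- seq(0, max(d) * (1 + 1e-9), length.out = 11)
  bin <- cut(d, breaks = bin_edges, include.lowest = TRUE, labels = FALSE)
  nb <- length(bin_edges) - 1L
  mean_by_bin <- function(v, keep = rep(TRUE, length(v))) {
    out <- rep(NA_real_, nb)
    agg <- tapply(v[keep & !is.na(bin)], bin[keep & !is.na(bin)], mean)
    out[as.integer(names(agg))] <- agg
    out
  }
  res <- list(
    bin_edges = bin_edges,
    bin_mid = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
    mean_weight = mean_by_bin(w),
    mean_abs_weight = mean_by_bin(abs(w)),
    n_pairs = tabulate(bin, nbins = nb),
    class_thresholds = class_thresholds)
  if (!is.null(hemisphere)) {
    same <- (outer(hemisphere, hemisphere, "=="))[up]
    res$mean_weight_within <- mean_by_bin(w, same)
    res$mean_weight_between <- mean_by_bin(w, !same)
  }
  tn <- class_thresholds[[1]]; ts <- class_thresholds[[2]]
  cls <- ifelse(w < -tn, "anticorrelation",
                ifelse(abs(w) <= tn, "neutral",
                       ifelse(w <= ts, "weak_positive", "strong_positive")))
  classes <- c("strong_positive", "weak_positive", "neutral",
               "anticorrelation")
  props <- matrix(NA_real_, 4, nb, dimnames = list(classes, NULL))
  for (b in seq_len(nb)) {
    in_bin <- which(bin == b)
    if (length(in_bin))
      props[, b] <- vapply(classes, function(cl)
        mean(cls[in_bin] == cl), 1)
  }
  res$class_proportions <- props
  base::structure(res, class = "geometry_profile")
}

#' Log-linear decay slope of a geometry profile
#'
#' Regresses `log(mean |weight|)` on bin-center distance over bins whose mean
#' absolute weight exceeds `min_abs_weight` (bins at the correlation noise
#' floor carry no slope information), returning the fitted slope.
#'
#' @param profile A `geometry_profile` from [distance_profile()].
#' @param min_abs_weight Floor below which bins are excluded.
#' @return Slope (per pixel; negative under exponential decay).
#' @export
decay_slope <- function(profile, min_abs_weight = 0.05) {
  keep <- !is.na(profile$mean_abs_weight) &
    profile$mean_abs_weight > min_abs_weight
  if (sum(keep) < 3)
    stop_mesoconn("fewer than 3 usable bins for slope fit",
                  class = "invalid_argument")
  unname(stats::coef(stats::lm(log(profile$mean_abs_weight[keep]) ~
                                 profile$bin_mid[keep]))[2])
}

#' Similarity of left and right within-hemisphere connectivity
#'
#' Pearson correlation between the left within-hemisphere edge weights and
#' the homotopically reordered right within-hemisphere edge weights.
#'
#' @param A An [fc_network()] over parcels.
#' @param parcellation A `parcellation` with hemisphere labels and homotopic
#'   partners (see [run_parcellation()]).
#' @return Pearson r.
#' @export
hemisphere_similarity <- function(A, parcellation) {
  W <- fc_weights(A)
  hemi <- parcellation$parcel_hemisphere
  partner <- parcellation$homotopic_partner
  if (is.null(hemi) || is.null(partner))
    stop_mesoconn("parcellation lacks hemisphere/homotopic information",
                  class = "invalid_argument")
  L <- which(hemi == "L")
  R <- partner[L]
  if (anyNA(R)) stop_mesoconn("missing homotopic partner",
                              class = "invalid_argument")
  lw <- W[L, L][upper.tri(diag(length(L)))]
  rw <- W[R, R][upper.tri(diag(length(L)))]
  stats::cor(lw, rw)
}

#' Mantel permutation test between two symmetric matrices
#'
#' Observed statistic: Pearson correlation of upper-triangle elements.
#' Null: simultaneous random row/column permutations of `B`; one-sided
#' p-value `(1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#'
#' @param A,B Symmetric matrices of equal size.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return List with `r` and `p`.
#' @export
mantel_test <- function(A, B, n_perm = 9999L, seed = 1L) {
  A <- fc_weights(A); B <- fc_weights(B)
  if (!all(dim(A) == dim(B)))
    stop_mesoconn("matrices must share dimensions",
                  class = "invalid_argument")
  if (n_perm < 1)
    stop_mesoconn("n_perm must be >= 1", class = "invalid_argument")
  up <- upper.tri(A)
  a <- A[up]
  r_obs <- stats::cor(a, B[up])
  n <- nrow(A)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    stats::cor(a, B[idx, idx][up])
  }, 1))
  list(r = r_obs, p = (1 + sum(r_perm >= r_obs)) / (1 + n_perm))
}

#' Pairwise similarity of networks, with self-versus-other summary
#'
#' Correlates the upper-triangle weights of every pair of networks. When
#' both subject and condition labels are given, also reports mean
#' self-similarity (same subject, different conditions) and mean
#' intersubject similarity (different subjects, spontaneous-to-spontaneous
#' when available, otherwise all cross-subject pairs), the fingerprinting
#' contrast.
#'
#' @param networks List of [fc_network()]s or matrices over a shared N.
#' @param subjects,conditions Optional per-network labels.
#' @return A `similarity_report`: list with `pairwise_r` (symmetric, unit
#'   diagonal), `subjects`, `conditions`, and when labels allow:
#'   `self_similarity_mean`, `intersubject_similarity_mean`,
#'   `intersubject_spontaneous_mean`, `intercondition_mean`.
#' @export
similarity_report <- function(networks, subjects = NULL, conditions = NULL) {
  mats <- lapply(networks, fc_weights)
  ns <- vapply(mats, nrow, 1L)
  if (length(unique(ns)) != 1L)
    stop_mesoconn("networks differ in node count",
                  class = "incompatible_networks")
  K <- length(mats)
  up <- upper.tri(mats[[1]])
  V <- vapply(mats, function(m) m[up], numeric(sum(up)))
  R <- suppressWarnings(stats::cor(V))
  diag(R) <- 1
  out <- list(pairwise_r = R, subjects = subjects, conditions = conditions)
  if (!is.null(subjects) && !is.null(conditions)) {
    same_subj <- outer(subjects, subjects, "==")
    same_cond <- outer(conditions, conditions, "==")
    upK <- upper.tri(R)
    self_pairs <- upK & same_subj & !same_cond
    other_pairs <- upK & !same_subj
    if (any(self_pairs))
      out$self_similarity_mean <- mean(R[self_pairs])
    if (any(other_pairs))
      out$intersubject_similarity_mean <- mean(R[other_pairs])
    spont <- conditions == "spontaneous"
    sp_pairs <- upK & !same_subj & outer(spont, spont, "&")
    if (any(sp_pairs))
      out$intersubject_spontaneous_mean <- mean(R[sp_pairs])
  }
  if (!is.null(conditions) && (is.null(subjects) ||
                               length(unique(subjects)) == 1L)) {
    upK <- upper.tri(R)
    out$intercondition_mean <- mean(R[upK])
  }
  base::structure(out, class = "similarity_report")
}

#' Correlation between node flexibility and participation
#'
#' Pearson correlation of per-node mean flexibility (stimulus-evoked
#' reconfiguration) with per-node participation (spontaneous connector
#' hubness).
#'
#' @param flex Numeric vector, `flexibility_profile`, or
#'   [flexibility_summary()] output.
#' @param participation Numeric vector or [hierarchy_participation()] output.
#' @return Pearson r.
#' @export
flexibility_participation_correlation <- function(flex, participation) {
  f <- if (is.list(flex)) (flex$f_mean %||% flex$f) else flex
  p <- if (is.list(participation)) participation$mean else participation
  if (length(f) != length(p))
    stop_mesoconn("length mismatch", class = "invalid_argument")
  if (stats::sd(f) == 0 || stats::sd(p) == 0)
    stop_mesoconn("constant vector: correlation undefined",
                  class = "undefined_correlation")
  stats::cor(f, p)
}
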