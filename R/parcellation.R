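#' Parameters of the multistage parcellation
#'
#' @param k_spatial Spatial k-means clusters per hemisphere.
#' @param k_functional Functional clusters of spatial clusters.
#' @param n_replicates k-means replicates (best by within-cluster SS).
#' @param max_diameter Maximum parcel diameter (pixels): largest pairwise
#'   distance among a parcel's member spatial-cluster centroids.
#' @param min_gap Minimum separation (pixels) between parcels carved from
#'   the same functional cluster.
#' @param seed Integer seed for all clustering stages.
#' @return An object of class `parcellation_params`.
#' @export
parcellation_params <- function(k_spatial = 2500L, k_functional = 100L,
                                n_replicates = 10L, max_diameter = 200,
                                min_gap = 60, seed = 1L) {
  if (!(max_diameter > min_gap && min_gap > 0))
    stop_mesoconn("need max_diameter > min_gap > 0", class = "invalid_spec")
  if (k_functional > k_spatial)
    stop_mesoconn("k_functional cannot exceed k_spatial",
                  class = "infeasible_clustering")
  base::structure(
    list(k_spatial = as.integer(k_spatial),
         k_functional = as.integer(k_functional),
         n_replicates = as.integer(n_replicates),
         max_diameter = max_diameter, min_gap = min_gap,
         seed = as.integer(seed)),
    class = "parcellation_params")
}

# Index of the nearest centroid for each point (squared Euclidean).
nearest_centroid <- function(points, centroids) {
  d2 <- matrix(rowSums(points^2), nrow(points), nrow(centroids)) +
    matrix(rowSums(centroids^2), nrow(points), nrow(centroids),
           byrow = TRUE) - 2 * points %*% t(centroids)
  max.col(-d2, ties.method = "first")
}

#' Spatial k-means of pooled left-hemisphere cell coordinates
#'
#' Euclidean k-means into `k_spatial` clusters, best of `n_replicates` by
#' within-cluster sum of squares, followed by a Voronoi reassignment so every
#' point is assigned to its nearest returned centroid.
#'
#' @param left_positions Matrix of left-hemisphere cell coordinates pooled
#'   over subjects.
#' @param params A [parcellation_params()].
#' @return A `spatial_clustering`: list with `centroids` (k x 3),
#'   `assignment` (per input point), `k`, `withinss`.
#' @export
spatial_kmeans_left <- function(left_positions, params) {
  left_positions <- as.matrix(left_positions)
  k <- params$k_spatial
  if (nrow(left_positions) < k)
    stop_mesoconn("fewer points (", nrow(left_positions),
                  ") than k_spatial (", k, ")",
                  class = "infeasible_clustering")
  km <- with_seed(params$seed,
                  suppressWarnings(stats::kmeans(
                    left_positions, centers = k,
                    nstart = params$n_replicates, iter.max = 100)))
  assignment <- nearest_centroid(left_positions, km$centers)
  base::structure(
    list(centroids = unname(km$centers), assignment = assignment, k = k,
         withinss = km$tot.withinss),
    class = "spatial_clustering")
}

#' Mirror a left-hemisphere clustering onto the right hemisphere
#'
#' Reflects the left centroids about the midline plane and assigns each
#' right-hemisphere cell to its nearest mirrored centroid. Cluster `i` (left)
#' and cluster `k + i` (right) are homotopic partners.
#'
#' @param left_clustering A `spatial_clustering` from [spatial_kmeans_left()].
#' @param right_positions Right-hemisphere cell coordinates.
#' @param midline_axis Index of the mirrored coordinate.
#' @return A `spatial_clustering` over both hemispheres: `centroids`
#'   (2k x 3), `right_assignment` (cluster ids `k+1 .. 2k`), `homotopic_map`,
#'   `k`, plus the left fields.
#' @export
mirror_assign <- function(left_clustering, right_positions,
                          midline_axis = 2L) {
  stopifnot(inherits(left_clustering, "spatial_clustering"))
  right_positions <- as.matrix(right_positions)
  if (nrow(right_positions) == 0L)
    stop_mesoconn("no right-hemisphere cells", class = "degenerate_input")
  mirrored <- left_clustering$centroids
  mirrored[, midline_axis] <- -mirrored[, midline_axis]
  k <- left_clustering$k
  right_assignment <- nearest_centroid(right_positions, mirrored) + k
  base::structure(
    list(centroids = rbind(left_clustering$centroids, mirrored),
         assignment = left_clustering$assignment,
         right_assignment = right_assignment,
         homotopic_map = c(seq_len(k) + k, seq_len(k)),
         k = k, withinss = left_clustering$withinss),
    class = "spatial_clustering")
}

#' Regress the global signal out of every trace
#'
#' Least-squares regression of each cell's trace on an intercept and the
#' mean-over-cells trace; returns the residuals, which are exactly
#' orthogonal to the global signal.
#'
#' @param traces Cells x frames matrix (typically spontaneous and stimulus
#'   recordings concatenated in time).
#' @return Residual matrix of the same shape (rows are mean-centered).
#' @export
global_signal_regression <- function(traces) {
  traces <- as.matrix(traces)
  g <- colMeans(traces)
  gc <- g - mean(g)
  den <- sum(gc^2)
  if (den == 0)
    stop_mesoconn("global signal has zero variance",
                  class = "ill_posed_regression")
  xc <- traces - rowMeans(traces)
  # a numerically negligible global signal (e.g. after a previous pass) has
  # an arbitrary normalized direction; regressing on it would remove an
  # arbitrary trace component, so treat it as already removed
  if (den <= 1e-12 * mean(xc^2) * length(g)) return(xc)
  beta <- as.numeric(xc %*% gc) / den
  xc - outer(beta, gc)
}

#' Functional k-means of spatial clusters by correlation distance
#'
#' Clusters the rows of the group- and hemisphere-averaged correlation
#' matrix with distance `1 - r` between rows. Implemented by z-scoring each
#' row and running Euclidean k-means (squared Euclidean distance of z-scored
#' rows is proportional to correlation distance), best of `n_replicates`.
#'
#' @param cluster_corr k x k correlation matrix among spatial-cluster traces.
#' @param params A [parcellation_params()].
#' @return Integer vector of functional labels (1..k_functional) per row.
#' @export
functional_kmeans <- function(cluster_corr, params) {
  cluster_corr <- as.matrix(cluster_corr)
  if (params$k_functional > nrow(cluster_corr))
    stop_mesoconn("k_functional exceeds number of rows",
                  class = "infeasible_clustering")
  z <- t(scale(t(cluster_corr)))
  if (any(!is.finite(z)))
    stop_mesoconn("constant row: correlation distance undefined",
                  class = "undefined_correlation")
  km <- with_seed(params$seed + 1L,
                  suppressWarnings(stats::kmeans(
                    z, centers = params$k_functional,
                    nstart = params$n_replicates, iter.max = 100)))
  as.integer(km$cluster)
}

group_diameter <- function(centroids, members) {
  if (length(members) < 2L) return(0)
  max(stats::dist(centroids[members, , drop = FALSE]))
}

group_gap <- function(centroids, a, b) {
  min(as.matrix(stats::dist(centroids[c(a, b), , drop = FALSE]))[
    seq_along(a), length(a) + seq_along(b), drop = FALSE])
}

# Split one oversized connected group by recursive bisecting 2-means.
bisect_group <- function(centroids, members, max_diameter, seed) {
  if (group_diameter(centroids, members) < max_diameter ||
      length(members) < 2L)
    return(list(members))
  pts <- centroids[members, , drop = FALSE]
  cl <- with_seed(seed, suppressWarnings(
    stats::kmeans(pts, centers = 2L, nstart = 5L, iter.max = 100)$cluster))
  if (length(unique(cl)) < 2L) {
    # fall back: split along the widest coordinate at its median
    spread <- apply(pts, 2, function(v) diff(range(v)))
    ax <- which.max(spread)
    cl <- as.integer(pts[, ax] > stats::median(pts[, ax])) + 1L
    if (length(unique(cl)) < 2L)
      cl <- c(1L, rep(2L, length(members) - 1L))
  }
  c(bisect_group(centroids, members[cl == 1L], max_diameter, seed + 1L),
    bisect_group(centroids, members[cl == 2L], max_diameter, seed + 2L))
}

#' Carve spatially constrained parcels out of functional clusters
#'
#' Within each functional cluster: (1) single-linkage agglomeration of
#' member spatial-cluster centroids cut at `min_gap` yields spatially
#' connected groups mutually separated by more than `min_gap`; (2) any group
#' whose centroid diameter reaches `max_diameter` is split by recursive
#' bisecting 2-means; (3) a repair pass greedily re-merges group pairs
#' closer than `min_gap` whenever the merged diameter stays below
#' `max_diameter`. The resulting left-hemisphere groups, mirrored into both
#' hemispheres, are the parcels: left parcel `p` and right parcel `p + P`
#' are homotopic partners.
#'
#' @param functional_labels Functional label per left spatial cluster.
#' @param cluster_centroids Left spatial-cluster centroids (k x 3).
#' @param params A [parcellation_params()].
#' @param midline_axis Mirrored coordinate index.
#' @return List with `groups` (member spatial clusters per left parcel),
#'   `functional_of_parcel`, `centroids` (left parcel centroids),
#'   `centroids_mirrored`.
#' @export
enforce_spatial_constraints <- function(functional_labels,
                                        cluster_centroids, params,
                                        midline_axis = 2L) {
  cluster_centroids <- as.matrix(cluster_centroids)
  stopifnot(length(functional_labels) == nrow(cluster_centroids))
  groups <- list()
  fun_of <- integer(0)
  for (fl in sort(unique(functional_labels))) {
    members <- which(functional_labels == fl)
    if (length(members) == 1L) {
      comp <- list(members)
    } else {
      hc <- stats::hclust(stats::dist(
        cluster_centroids[members, , drop = FALSE]), method = "single")
      cut <- stats::cutree(hc, h = params$min_gap)
      comp <- split(members, cut)
    }
    # diameter-driven subdivision
    comp <- unlist(lapply(seq_along(comp), function(i)
      bisect_group(cluster_centroids, comp[[i]], params$max_diameter,
                   seed = params$seed + 100L * i)), recursive = FALSE)
    # repair: re-merge sub-min_gap pairs while diameter allows
    repeat {
      if (length(comp) < 2L) break
      ng <- length(comp)
      best <- NULL
      for (a in seq_len(ng - 1L)) for (b in seq((a + 1L), ng)) {
        gp <- group_gap(cluster_centroids, comp[[a]], comp[[b]])
        if (gp < params$min_gap &&
            group_diameter(cluster_centroids,
                           c(comp[[a]], comp[[b]])) < params$max_diameter &&
            (is.null(best) || gp < best$gap))
          best <- list(a = a, b = b, gap = gp)
      }
      if (is.null(best)) break
      comp[[best$a]] <- c(comp[[best$a]], comp[[best$b]])
      comp[[best$b]] <- NULL
    }
    groups <- c(groups, comp)
    fun_of <- c(fun_of, rep(fl, length(comp)))
  }
  cent <- t(vapply(groups, function(m)
    colMeans(cluster_centroids[m, , drop = FALSE]), numeric(3)))
  cent_m <- cent
  cent_m[, midline_axis] <- -cent_m[, midline_axis]
  list(groups = groups, functional_of_parcel = fun_of, centroids = cent,
       centroids_mirrored = cent_m)
}

#' Run the full multistage parcellation on a study dataset
#'
#' Orchestrates: pooled left-hemisphere spatial k-means, mirroring onto the
#' right hemisphere, global signal regression of condition-concatenated
#' traces, spatial-cluster trace averaging, group- and hemisphere-averaged
#' correlation, functional k-means, and spatial-constraint enforcement.
#' Deterministic given the params seed.
#'
#' @param dataset A `study_dataset` (see [generate_study()]).
#' @param params A [parcellation_params()].
#' @return A `parcellation`: list with `n_parcels`, `parcel_of_cell`,
#'   `parcel_centroids`, `parcel_hemisphere`, `homotopic_partner`,
#'   `parcel_functional`, `groups` (left-parcel spatial-cluster members),
#'   `spatial` (the two-hemisphere `spatial_clustering`), `cell_counts`,
#'   `frac_parcels_all_subjects`, `params`.
#' @export
run_parcellation <- function(dataset, params) {
  stopifnot(inherits(dataset, "study_dataset"),
            inherits(params, "parcellation_params"))
  mid <- dataset$populations[[1]]$midline_axis
  pos <- dataset$populations[[1]]$positions
  hemi <- dataset$populations[[1]]$hemisphere
  left_idx <- which(hemi == "L")
  right_idx <- which(hemi == "R")

  pooled_left <- do.call(rbind, lapply(dataset$populations, function(p)
    p$positions[p$hemisphere == "L", , drop = FALSE]))
  sc_left <- spatial_kmeans_left(pooled_left, params)
  sc <- mirror_assign(sc_left, pos[right_idx, , drop = FALSE],
                      midline_axis = mid)
  k <- sc$k

  # per-cell spatial cluster for the shared aligned population
  cell_cluster <- integer(nrow(pos))
  cell_cluster[left_idx] <- nearest_centroid(
    pos[left_idx, , drop = FALSE], sc$centroids[seq_len(k), , drop = FALSE])
  cell_cluster[right_idx] <- sc$right_assignment

  # group- and hemisphere-averaged correlation among spatial clusters
  corr_sum <- matrix(0, k, k)
  n_terms <- 0L
  for (s in seq_along(dataset$recordings)) {
    concat <- do.call(cbind, lapply(dataset$conditions, function(cond)
      dataset$recordings[[s]][[cond]]$traces))
    resid <- global_signal_regression(concat)
    ct <- parcel_average_traces(resid, cell_cluster, on_empty = "drop")
    kept <- attr(ct, "kept_parcels")
    full <- matrix(NA_real_, 2L * k, ncol(ct))
    full[kept, ] <- ct
    rl <- suppressWarnings(stats::cor(t(full[seq_len(k), , drop = FALSE])))
    rr <- suppressWarnings(stats::cor(t(full[k + seq_len(k), ,
                                             drop = FALSE])))
    for (m in list(rl, rr)) {
      m[is.na(m)] <- 0
      corr_sum <- corr_sum + m
      n_terms <- n_terms + 1L
    }
  }
  avg_corr <- corr_sum / n_terms
  diag(avg_corr) <- 1

  fun_labels <- functional_kmeans(avg_corr, params)
  carve <- enforce_spatial_constraints(fun_labels,
                                       sc$centroids[seq_len(k), ,
                                                    drop = FALSE],
                                       params, midline_axis = mid)
  P <- length(carve$groups)

  # left parcels 1..P, right parcels P+1..2P (homotopic mirror images)
  parcel_of_left_cluster <- integer(k)
  for (p in seq_len(P)) parcel_of_left_cluster[carve$groups[[p]]] <- p
  parcel_of_cell <- integer(nrow(pos))
  parcel_of_cell[left_idx] <-
    parcel_of_left_cluster[cell_cluster[left_idx]]
  parcel_of_cell[right_idx] <-
    parcel_of_left_cluster[cell_cluster[right_idx] - k] + P

  centroids <- rbind(carve$centroids, carve$centroids_mirrored)
  counts <- tabulate(parcel_of_cell, nbins = 2L * P)
  base::structure(
    list(n_parcels = 2L * P,
         parcel_of_cell = parcel_of_cell,
         parcel_centroids = centroids,
         parcel_hemisphere = rep(c("L", "R"), each = P),
         homotopic_partner = c(seq_len(P) + P, seq_len(P)),
         parcel_functional = rep(carve$functional_of_parcel, 2L),
         groups = carve$groups,
         spatial = sc,
         cell_counts = counts,
         frac_parcels_all_subjects = mean(counts > 0L),
         params = params),
    class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "parcellation: %d parcels (%d per hemisphere), %d cells, median %d cells/parcel\n",
    x$n_parcels, x$n_parcels %/% 2L, length(x$parcel_of_cell),
    as.integer(stats::median(x$cell_counts))))
  invisible(x)
}
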