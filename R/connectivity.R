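#' Construct a functional-connectivity network object
#'
#' A signed, weighted network of Fisher-transformed Pearson correlations
#' between node (parcel) activity traces: symmetric weight matrix with zero
#' diagonal, plus node centroid coordinates.
#'
#' @param weights N x N symmetric numeric matrix, zero diagonal, finite.
#' @param coords Optional N x 3 matrix of node centroids (pixels).
#' @param condition Condition label.
#' @param subject_id Subject identifier (or `"group"`).
#' @return An object of class `fc_network`.
#' @export
fc_network <- function(weights, coords = NULL, condition = NA_character_,
                       subject_id = NA_character_) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop_mesoconn("weights must be square", class = "invalid_network")
  if (any(!is.finite(weights)))
    stop_mesoconn("weights must be finite", class = "invalid_network")
  if (max(abs(weights - t(weights))) > 1e-8)
    stop_mesoconn("weights must be symmetric", class = "invalid_network")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != nrow(weights))
      stop_mesoconn("coords row count must match weights",
                    class = "invalid_network")
  }
  base::structure(
    list(weights = weights, coords = coords, condition = condition,
         subject_id = subject_id),
    class = "fc_network")
}

#' @export
print.fc_network <- function(x, ...) {
  cat(sprintf("fc_network: %d nodes (condition=%s, subject=%s)\n",
              nrow(x$weights), x$condition, x$subject_id))
  invisible(x)
}

fc_weights <- function(A) {
  if (inherits(A, "fc_network")) A$weights else as.matrix(A)
}

#' Fisher z-transform of correlation coefficients
#'
#' `atanh(r)`, with `r` numerically at +/-1 clipped to +/-(1 - 1e-12) so the
#' transform stays finite.
#'
#' @param r Correlations in `[-1, 1]`.
#' @return Fisher-z values.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

#' Average node traces over parcel members
#'
#' Row `p` of the result is the mean fluorescence trace of the cells assigned
#' to parcel `p`. Parcels with no member cells are an error unless
#' `on_empty = "drop"`, in which case they are removed and recorded in the
#' `"kept_parcels"` attribute.
#'
#' @param recording A `fluorescence_recording`, or a cells x frames matrix.
#' @param parcellation A `parcellation` (see [run_parcellation()]), or an
#'   integer vector mapping each cell to a parcel id.
#' @param on_empty `"error"` or `"drop"`.
#' @return N x T matrix of parcel-averaged traces.
#' @export
parcel_average_traces <- function(recording, parcellation,
                                  on_empty = c("error", "drop")) {
  on_empty <- match.arg(on_empty)
  traces <- if (inherits(recording, "fluorescence_recording"))
    recording$traces else as.matrix(recording)
  parcel_of_cell <- if (inherits(parcellation, "parcellation"))
    parcellation$parcel_of_cell else as.integer(parcellation)
  n_parcels <- if (inherits(parcellation, "parcellation"))
    parcellation$n_parcels else max(parcel_of_cell)
  if (length(parcel_of_cell) != nrow(traces))
    stop_mesoconn("parcel map length must equal number of cells",
                  class = "invalid_parcellation")
  counts <- tabulate(parcel_of_cell, nbins = n_parcels)
  empty <- which(counts == 0L)
  if (length(empty) && on_empty == "error")
    stop_mesoconn("parcel(s) with no cells: ",
                  paste(empty, collapse = ", "), class = "empty_parcel")
  sums <- rowsum(traces, parcel_of_cell, reorder = TRUE)
  out <- matrix(NA_real_, n_parcels, ncol(traces))
  out[as.integer(rownames(sums)), ] <- sums / counts[counts > 0L]
  kept <- setdiff(seq_len(n_parcels), empty)
  out <- out[kept, , drop = FALSE]
  attr(out, "kept_parcels") <- kept
  out
}

#' Compute a signed Fisher-z functional-connectivity network
#'
#' Pairwise Pearson correlations between rows of `parcel_traces`, Fisher
#' transformed, with the diagonal set to zero.
#'
#' @param parcel_traces N x T matrix (rows are node traces, T >= 3).
#' @param coords Optional node coordinates carried into the network.
#' @param condition,subject_id Metadata labels.
#' @return An [fc_network()].
#' @export
compute_fc <- function(parcel_traces, coords = NULL,
                       condition = NA_character_,
                       subject_id = NA_character_) {
  parcel_traces <- as.matrix(parcel_traces)
  if (ncol(parcel_traces) < 3)
    stop_mesoconn("need at least 3 frames", class = "invalid_traces")
  sds <- apply(parcel_traces, 1, stats::sd)
  if (any(sds == 0))
    stop_mesoconn("constant trace for parcel(s): ",
                  paste(which(sds == 0), collapse = ", "),
                  class = "undefined_correlation")
  r <- stats::cor(t(parcel_traces))
  z <- fisher_z(r)
  diag(z) <- 0
  fc_network(z, coords = coords, condition = condition,
             subject_id = subject_id)
}

#' Phase-randomize a set of traces (one surrogate)
#'
#' Computes each trace's discrete Fourier transform, adds independent uniform
#' random phase offsets to the positive-frequency bins (conjugate-symmetric
#' on the negative frequencies; DC and Nyquist bins untouched so the signal
#' stays real), and inverts the transform. The amplitude spectrum — hence
#' mean and variance — of every trace is preserved exactly, while
#' cross-correlations between traces are destroyed.
#'
#' @param traces n x T matrix.
#' @param seed Optional integer seed.
#' @param phases Optional (n x n_pos) matrix of phase offsets for the
#'   positive-frequency bins, bypassing the RNG (all-zero phases return the
#'   input exactly).
#' @return n x T matrix of surrogate traces.
#' @export
phase_randomize <- function(traces, seed = NULL, phases = NULL) {
  traces <- as.matrix(traces)
  n <- nrow(traces); T <- ncol(traces)
  if (T < 4) stop_mesoconn("need at least 4 frames", class = "invalid_traces")
  half <- (T - 1) %/% 2               # strictly positive, non-Nyquist bins
  pos_bins <- seq_len(half) + 1L
  if (is.null(phases)) {
    draw <- function() matrix(stats::runif(n * half, 0, 2 * pi), n, half)
    phases <- if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  out <- matrix(0, n, T)
  for (i in seq_len(n)) {
    X <- stats::fft(traces[i, ])
    rot <- exp(1i * phases[i, ])
    X[pos_bins] <- X[pos_bins] * rot
    X[T + 2L - pos_bins] <- Conj(X[pos_bins])
    out[i, ] <- Re(stats::fft(X, inverse = TRUE)) / T
  }
  out
}

#' Generate an ensemble of phase-randomized surrogate trace sets
#'
#' @param parcel_traces n x T matrix of source traces.
#' @param n_surrogates Number of surrogates (>= 1).
#' @param seed Integer seed; surrogate `k` uses an independently derived
#'   sub-seed so the ensemble is reproducible.
#' @return List of n x T surrogate matrices.
#' @export
phase_randomized_surrogates <- function(parcel_traces, n_surrogates,
                                        seed = 1L) {
  if (n_surrogates < 1)
    stop_mesoconn("n_surrogates must be >= 1", class = "invalid_argument")
  seeds <- derive_seeds(seed, n_surrogates)
  lapply(seq_len(n_surrogates), function(k)
    phase_randomize(parcel_traces, seed = seeds[[k]]))
}

#' Element-wise average of functional-connectivity networks
#'
#' @param networks List of [fc_network()]s sharing node count and coordinates.
#' @return An [fc_network()] with the mean Fisher-z weights; condition and
#'   subject labels are kept if shared, otherwise set to `"group"`.
#' @export
group_average <- function(networks) {
  stopifnot(length(networks) >= 1)
  ns <- vapply(networks, function(x) nrow(fc_weights(x)), 1L)
  if (length(unique(ns)) != 1L)
    stop_mesoconn("networks differ in node count",
                  class = "incompatible_networks")
  W <- Reduce(`+`, lapply(networks, fc_weights)) / length(networks)
  conds <- unique(vapply(networks, function(x)
    if (inherits(x, "fc_network")) x$condition else NA_character_, ""))
  coords <- NULL
  for (x in networks)
    if (inherits(x, "fc_network") && !is.null(x$coords)) {
      coords <- x$coords
      break
    }
  fc_network(W, coords = coords,
             condition = if (length(conds) == 1L) conds else NA_character_,
             subject_id = "group")
}
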