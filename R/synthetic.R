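#' Specification of a synthetic brain-shaped cell cloud
#'
#' Describes the geometry of a hemispherically symmetric population of cells
#' used by [generate_cells()]. Cells fill an ellipsoid (axis units are image
#' pixels, matching the coordinate frame of registered light-sheet volumes);
#' one hemisphere is sampled uniformly and reflected about the midline plane
#' so that mirror symmetry is exact by construction.
#'
#' @param n_cells_per_hemisphere Number of cells in each hemisphere.
#' @param ellipsoid_semi_axes Semi-axes (pixels) of the bounding ellipsoid,
#'   ordered rostrocaudal, mediolateral, dorsoventral.
#' @param midline_axis Index (1-3) of the coordinate mirrored at the midline.
#' @param seed Integer seed controlling cell placement.
#' @return An object of class `synthetic_brain_spec`.
#' @export
synthetic_brain_spec <- function(n_cells_per_hemisphere = 1000,
                                 ellipsoid_semi_axes = c(500, 200, 150),
                                 midline_axis = 2L,
                                 seed = 1L) {
  if (!is.numeric(n_cells_per_hemisphere) || length(n_cells_per_hemisphere) != 1L ||
      n_cells_per_hemisphere < 1)
    stop_mesoconn("n_cells_per_hemisphere must be a positive integer",
                  class = "invalid_spec")
  if (!is.numeric(ellipsoid_semi_axes) || length(ellipsoid_semi_axes) != 3L ||
      any(!is.finite(ellipsoid_semi_axes)) || any(ellipsoid_semi_axes <= 0))
    stop_mesoconn("ellipsoid_semi_axes must be 3 positive numbers",
                  class = "invalid_spec")
  if (!midline_axis %in% 1:3)
    stop_mesoconn("midline_axis must be 1, 2 or 3", class = "invalid_spec")
  structure(
    list(n_cells_per_hemisphere = as.integer(n_cells_per_hemisphere),
         ellipsoid_semi_axes = as.numeric(ellipsoid_semi_axes),
         midline_axis = as.integer(midline_axis),
         seed = as.integer(seed)),
    class = "synthetic_brain_spec")
}

#' Generate an aligned, hemispherically symmetric cell population
#'
#' Rejection-samples `n_cells_per_hemisphere` uniform points inside the left
#' half of the spec's ellipsoid (midline coordinate < 0) and mirrors them to
#' obtain the right hemisphere, so every left cell has an exact mirror-image
#' right partner: cell `i` (L) is paired with cell `i + n` (R).
#'
#' @param spec A [synthetic_brain_spec()].
#' @param subject_id Identifier attached to the population.
#' @return A `cell_population`: list with `positions` (2n x 3 matrix, pixels),
#'   `hemisphere` (`"L"`/`"R"`), `midline_axis`, and `subject_id`.
#' @export
generate_cells <- function(spec, subject_id = "subject1") {
  stopifnot(inherits(spec, "synthetic_brain_spec"))
  n <- spec$n_cells_per_hemisphere
  ax <- spec$ellipsoid_semi_axes
  mid <- spec$midline_axis
  left <- with_seed(spec$seed, {
    pts <- matrix(NA_real_, 0, 3)
    while (nrow(pts) < n) {
      cand <- cbind(runif(2L * n, -ax[1], ax[1]),
                    runif(2L * n, -ax[2], ax[2]),
                    runif(2L * n, -ax[3], ax[3]))
      inside <- rowSums(sweep(cand, 2, ax, "/")^2) <= 1
      keep <- inside & cand[, mid] < 0
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts[seq_len(n), , drop = FALSE]
  })
  right <- left
  right[, mid] <- -right[, mid]
  structure(
    list(positions = rbind(left, right),
         hemisphere = rep(c("L", "R"), each = n),
         midline_axis = mid,
         subject_id = subject_id),
    class = "cell_population")
}

#' Planted statistical structure for synthetic recordings
#'
#' Defines the ground truth that [generate_activity()] embeds in fluorescence
#' traces: a two-level module hierarchy (coarse modules containing fine
#' modules, laid out spatially by k-means on midline-folded coordinates so
#' modules are hemispherically symmetric and spatially compact), nested
#' equicorrelation levels, an exponential distance-decay background field, a
#' shared global signal, and a designated set of flexible cells that change
#' fine-module allegiance under non-spontaneous stimulus conditions.
#'
#' Correlation targets follow a nested equicorrelation construction: a pair in
#' the same fine module has structured covariance `within_fine_corr`, same
#' coarse but different fine `within_coarse_corr`, different coarse
#' `between_corr * exp(-decay_rate * distance)`. With `global_amp = 0` and
#' `noise_sd = sqrt(1 - within_fine_corr)` these are attained exactly in
#' expectation (traces then have unit variance).
#'
#' Flexible cells, under spontaneous conditions, split their fine-module
#' loading between their own module and their stimulus remap targets
#' (`connector_mix` controls the split), which makes them planted connector
#' hubs as well as planted flexible nodes. `subject_loading_sd` adds a
#' per-subject random fine-module coupling matrix through which every cell
#' loads on all fine-module latents (constant within a module, so it is not
#' averaged away by parcellation), drawn once per subject and reused across
#' conditions, giving each subject a stable connectivity fingerprint.
#'
#' @param cells A `cell_population` from [generate_cells()].
#' @param n_coarse,n_fine_per_coarse Module counts for the two levels.
#' @param within_fine_corr,within_coarse_corr,between_corr Target correlations,
#'   strictly decreasing, in `[0, 1)`.
#' @param decay_rate Spatial decay constant (per pixel) of the background
#'   correlation field.
#' @param global_amp Mixing weight of the shared global signal.
#' @param noise_sd Standard deviation of per-cell independent noise.
#' @param flexible_cells Integer indices of flexible cells, or `NULL` to use
#'   every cell of fine module `flexible_module`.
#' @param flexible_module Fine module whose cells are flexible by default.
#' @param conditions Condition labels; must include `"spontaneous"`.
#' @param condition_remap Named integer vector: for each non-spontaneous
#'   condition, the fine module flexible cells are reassigned to. `NULL`
#'   cycles deterministically through the other fine modules.
#' @param subject_loading_sd Scale of the per-subject module-coupling
#'   perturbation (0 disables the subject fingerprint).
#' @param connector_mix Fraction (0-1) of a flexible cell's spontaneous
#'   fine-module variance placed on its remap targets.
#' @param seed Integer seed for the module layout.
#' @return An object of class `planted_structure`.
#' @export
planted_structure <- function(cells,
                              n_coarse = 2L,
                              n_fine_per_coarse = 2L,
                              within_fine_corr = 0.6,
                              within_coarse_corr = 0.3,
                              between_corr = 0.1,
                              decay_rate = 0.004,
                              global_amp = 0.2,
                              noise_sd = sqrt(1 - within_fine_corr),
                              flexible_cells = NULL,
                              flexible_module = 1L,
                              conditions = c("spontaneous", "PT", "OMR",
                                             "Looming", "DF"),
                              condition_remap = NULL,
                              subject_loading_sd = 0.5,
                              connector_mix = 0.5,
                              seed = 1L) {
  stopifnot(inherits(cells, "cell_population"))
  if (!(within_fine_corr > within_coarse_corr &&
        within_coarse_corr > between_corr && between_corr >= 0 &&
        within_fine_corr < 1))
    stop_mesoconn("need 1 > within_fine_corr > within_coarse_corr > ",
                  "between_corr >= 0", class = "invalid_spec")
  assert_scalar_number(decay_rate, "decay_rate")
  if (decay_rate < 0) stop_mesoconn("decay_rate must be >= 0",
                                    class = "invalid_spec")
  assert_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  if (global_amp < 0) stop_mesoconn("global_amp must be >= 0",
                                    class = "invalid_spec")
  if (!"spontaneous" %in% conditions)
    stop_mesoconn("conditions must include 'spontaneous'",
                  class = "invalid_spec")
  n_cells <- nrow(cells$positions)
  n_fine <- n_coarse * n_fine_per_coarse

  # Hemisphere-symmetric spatial module layout: k-means on midline-folded
  # coordinates assigns mirror pairs identically.
  folded <- cells$positions
  folded[, cells$midline_axis] <- abs(folded[, cells$midline_axis])
  assign_modules <- function() {
    coarse <- stats::kmeans(folded, centers = n_coarse, nstart = 10,
                            iter.max = 100)$cluster
    fine <- integer(n_cells)
    fine_to_coarse <- integer(n_fine)
    nxt <- 1L
    for (cm in seq_len(n_coarse)) {
      idx <- which(coarse == cm)
      if (n_fine_per_coarse == 1L) {
        sub <- rep(1L, length(idx))
      } else {
        sub <- stats::kmeans(folded[idx, , drop = FALSE],
                             centers = n_fine_per_coarse, nstart = 10,
                             iter.max = 100)$cluster
      }
      fine[idx] <- nxt + sub - 1L
      fine_to_coarse[nxt + seq_len(n_fine_per_coarse) - 1L] <- cm
      nxt <- nxt + n_fine_per_coarse
    }
    list(coarse = coarse, fine = fine, fine_to_coarse = fine_to_coarse)
  }
  mods <- with_seed(seed, assign_modules())

  if (is.null(flexible_cells))
    flexible_cells <- which(mods$fine == flexible_module)
  flexible_cells <- as.integer(flexible_cells)
  if (length(flexible_cells) && (min(flexible_cells) < 1 ||
                                 max(flexible_cells) > n_cells))
    stop_mesoconn("flexible_cells out of range", class = "invalid_spec")

  stim <- setdiff(conditions, "spontaneous")
  if (is.null(condition_remap)) {
    pool <- setdiff(seq_len(n_fine), flexible_module)
    if (length(pool) == 0L) pool <- flexible_module
    condition_remap <- stats::setNames(
      pool[(seq_along(stim) - 1L) %% length(pool) + 1L], stim)
  }
  condition_remap <- condition_remap[stim]
  if (length(stim) && any(is.na(condition_remap)))
    stop_mesoconn("condition_remap must name every non-spontaneous condition",
                  class = "invalid_spec")

  structure(
    list(coarse = mods$coarse, fine = mods$fine,
         fine_to_coarse = mods$fine_to_coarse,
         n_coarse = as.integer(n_coarse), n_fine = as.integer(n_fine),
         within_fine_corr = within_fine_corr,
         within_coarse_corr = within_coarse_corr,
         between_corr = between_corr,
         decay_rate = decay_rate, global_amp = global_amp,
         noise_sd = noise_sd,
         flexible_cells = flexible_cells,
         conditions = conditions,
         condition_remap = condition_remap,
         subject_loading_sd = subject_loading_sd,
         connector_mix = connector_mix,
         seed = as.integer(seed)),
    class = "planted_structure")
}

#' Ground-truth fine-module labels under a condition
#'
#' @param structure A [planted_structure()].
#' @param condition Condition label.
#' @return Integer vector of per-cell fine-module labels, with flexible cells
#'   remapped under non-spontaneous conditions.
#' @export
ground_truth_labels <- function(structure, condition = "spontaneous") {
  stopifnot(inherits(structure, "planted_structure"))
  labels <- structure$fine
  if (!identical(condition, "spontaneous")) {
    if (!condition %in% names(structure$condition_remap))
      stop_mesoconn("unknown condition '", condition, "'",
                    class = "unknown_condition")
    labels[structure$flexible_cells] <-
      structure$condition_remap[[condition]]
  }
  labels
}

# Cholesky factor (upper) of the exponential-decay spatial correlation kernel
# exp(-decay_rate * d_ij), with a small nugget for numerical rank safety.
spatial_field_chol <- function(positions, decay_rate) {
  K <- unname(exp(-decay_rate * as.matrix(stats::dist(positions))))
  diag(K) <- diag(K) + 1e-8
  chol(K)
}

#' Generate a synthetic fluorescence recording with planted structure
#'
#' Each cell's trace is a weighted sum of latent Gaussian module time series
#' (its fine and coarse module under the condition's ground truth), a
#' distance-decaying Gaussian background field, a shared global signal, and
#' independent noise:
#' `x_i = a_f v_fine(i) + a_c u_coarse(i) + a_b s_i + global_amp g + noise_sd e_i`
#' with `a_f = sqrt(rho_f - rho_c)`, `a_c = sqrt(rho_c - rho_b)`,
#' `a_b = sqrt(rho_b)` and `corr(s_i, s_j) = exp(-decay_rate * d_ij)`.
#' Flexible cells follow `condition_remap` under non-spontaneous conditions
#' and, under spontaneous conditions, spread `connector_mix` of their
#' fine-module variance over their remap targets.
#'
#' @param cells A `cell_population` (positions aligned across subjects).
#' @param structure A [planted_structure()].
#' @param n_frames Number of frames (>= 2).
#' @param condition Condition label (must be spontaneous or in the remap).
#' @param seed Integer seed.
#' @param subject_loadings Optional n_cells x n_fine matrix of per-subject
#'   extra loadings onto the fine-module latents (see [generate_study()]).
#' @param frame_rate Volumes per second (metadata only; zero-lag analyses).
#' @param spatial_chol Optional precomputed [spatial_field_chol()] factor.
#' @return A `fluorescence_recording`: list with `traces` (cells x frames),
#'   `frame_rate`, `condition`, `subject_id`.
#' @export
generate_activity <- function(cells, structure, n_frames,
                              condition = "spontaneous", seed = 1L,
                              subject_loadings = NULL, frame_rate = 2,
                              spatial_chol = NULL) {
  stopifnot(inherits(cells, "cell_population"),
            inherits(structure, "planted_structure"))
  if (n_frames < 2) stop_mesoconn("n_frames must be >= 2",
                                  class = "invalid_spec")
  n <- nrow(cells$positions)
  if (length(structure$fine) != n)
    stop_mesoconn("structure and cells disagree on cell count",
                  class = "invalid_spec")
  labels <- ground_truth_labels(structure, condition)

  rho_f <- structure$within_fine_corr
  rho_c <- structure$within_coarse_corr
  rho_b <- structure$between_corr
  a_f <- sqrt(rho_f - rho_c)
  a_c <- sqrt(rho_c - rho_b)
  a_b <- sqrt(rho_b)

  if (a_b > 0 && is.null(spatial_chol))
    spatial_chol <- spatial_field_chol(cells$positions, structure$decay_rate)

  traces <- with_seed(seed, {
    V <- matrix(stats::rnorm(structure$n_fine * n_frames),
                structure$n_fine, n_frames)
    U <- matrix(stats::rnorm(structure$n_coarse * n_frames),
                structure$n_coarse, n_frames)
    g <- stats::rnorm(n_frames)
    S <- if (a_b > 0) {
      crossprod(spatial_chol, matrix(stats::rnorm(n * n_frames), n, n_frames))
    } else NULL
    eps <- matrix(stats::rnorm(n * n_frames), n, n_frames)

    Fsig <- V[labels, , drop = FALSE]
    mix <- structure$connector_mix
    if (identical(condition, "spontaneous") && mix > 0 &&
        length(structure$flexible_cells)) {
      targets <- unique(unname(structure$condition_remap))
      targets <- setdiff(targets, NA_integer_)
      for (i in structure$flexible_cells) {
        own <- structure$fine[i]
        tg <- setdiff(targets, own)
        if (length(tg)) {
          Fsig[i, ] <- sqrt(1 - mix) * V[own, ] +
            sqrt(mix / length(tg)) * colSums(V[tg, , drop = FALSE])
        }
      }
    }
    Csig <- U[structure$fine_to_coarse[labels], , drop = FALSE]
    out <- a_f * Fsig + a_c * Csig +
      structure$global_amp * matrix(g, n, n_frames, byrow = TRUE) +
      structure$noise_sd * eps
    if (!is.null(S)) out <- out + a_b * S
    if (!is.null(subject_loadings)) out <- out + subject_loadings %*% V
    out
  })

  base::structure(
    list(traces = traces, frame_rate = frame_rate, condition = condition,
         subject_id = cells$subject_id),
    class = "fluorescence_recording")
}

#' Generate a multi-subject, multi-condition synthetic study
#'
#' All subjects share one aligned cell population and one planted structure;
#' latent signals and noise are drawn independently per subject and
#' condition, and each subject receives a stable random loading perturbation
#' (scale `subject_loading_sd`) reused across its conditions, so intersubject
#' functional-connectivity similarity is positive but below 1 and subjects
#' are more similar to themselves across conditions than to one another.
#'
#' @param spec A [synthetic_brain_spec()].
#' @param structure A [planted_structure()], or `NULL` to build one with
#'   defaults from the generated cells.
#' @param n_subjects Number of subjects (>= 1).
#' @param conditions Condition labels including `"spontaneous"`.
#' @param n_frames Frames per condition recording.
#' @param seed Master seed; per-subject and per-condition seeds are derived
#'   deterministically from it.
#' @return A `study_dataset`: list with `populations`, `recordings` (nested
#'   subject -> condition), `structure`, `conditions`, `spec`.
#' @export
generate_study <- function(spec, structure = NULL, n_subjects = 3L,
                           conditions = c("spontaneous", "PT", "OMR",
                                          "Looming", "DF"),
                           n_frames = 400L, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_brain_spec"))
  if (n_subjects < 1) stop_mesoconn("n_subjects must be >= 1",
                                    class = "invalid_spec")
  if (length(conditions) == 0L)
    stop_mesoconn("conditions must be non-empty", class = "invalid_spec")
  if (!"spontaneous" %in% conditions)
    stop_mesoconn("conditions must include 'spontaneous'",
                  class = "invalid_spec")

  cells <- generate_cells(spec)
  seeds <- derive_seeds(seed, 1L + n_subjects * (1L + length(conditions)))
  if (is.null(structure))
    structure <- planted_structure(cells, conditions = conditions,
                                   seed = seeds[[1L]])
  if (!all(conditions %in% structure$conditions))
    stop_mesoconn("structure does not cover all requested conditions",
                  class = "invalid_spec")

  sp_chol <- if (structure$between_corr > 0)
    spatial_field_chol(cells$positions, structure$decay_rate) else NULL

  n <- nrow(cells$positions)
  populations <- vector("list", n_subjects)
  recordings <- vector("list", n_subjects)
  k <- 2L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("subject%d", s)
    pop <- cells
    pop$subject_id <- sid
    populations[[s]] <- pop
    # Subject fingerprint: a subject-specific fine-module coupling matrix.
    # Loadings are constant within a fine module, so the perturbation is not
    # averaged away when cells are aggregated into parcels.
    E <- if (structure$subject_loading_sd > 0) {
      with_seed(seeds[[k]], {
        C <- matrix(stats::rnorm(structure$n_fine^2,
                                 sd = structure$subject_loading_sd /
                                   sqrt(structure$n_fine)),
                    structure$n_fine, structure$n_fine)
        C[structure$fine, , drop = FALSE]
      })
    } else NULL
    k <- k + 1L
    recs <- vector("list", length(conditions))
    names(recs) <- conditions
    for (cond in conditions) {
      recs[[cond]] <- generate_activity(
        pop, structure, n_frames = n_frames, condition = cond,
        seed = seeds[[k]], subject_loadings = E, spatial_chol = sp_chol)
      k <- k + 1L
    }
    recordings[[s]] <- recs
  }
  names(populations) <- vapply(populations, `[[`, "", "subject_id")
  names(recordings) <- names(populations)

  base::structure(
    list(populations = populations, recordings = recordings,
         structure = structure, conditions = conditions, spec = spec,
         seed = as.integer(seed)),
    class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "study_dataset: %d subjects x %d conditions, %d cells, %d frames/condition\n",
    length(x$populations), length(x$conditions),
    nrow(x$populations[[1]]$positions),
    ncol(x$recordings[[1]][[1]]$traces)))
  invisible(x)
}
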