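#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles every tunable of the synthetic study and its analysis. Defaults
#' are desk-scale: large enough for every statistic to be estimable, small
#' enough that the full pipeline runs in minutes on one CPU.
#'
#' @param n_cells_per_hemisphere,ellipsoid_semi_axes,midline_axis Geometry of
#'   the synthetic brain (see [synthetic_brain_spec()]).
#' @param n_subjects,conditions,n_frames Study layout (frames are per
#'   condition; see [generate_study()]).
#' @param structure_args Named list of overrides for [planted_structure()].
#' @param k_spatial,k_functional,n_replicates,max_diameter,min_gap
#'   Parcellation parameters (see [parcellation_params()]).
#' @param n_surrogates Phase-randomized surrogates per subject.
#' @param n_gamma Resolution samples for the single-layer hierarchy.
#' @param n_multilayer (gamma, omega) samples for the multilayer ensemble.
#' @param module_range Mean-modules-per-layer filter for flexibility
#'   averaging.
#' @param alpha Significance level for consensus splits.
#' @param n_perm_consensus Permutations per consensus split test.
#' @param n_perm_mantel Mantel permutations.
#' @param class_thresholds `c(t_neutral, t_strong)` for connection classes.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional directory for stage outputs (`NULL`: in-memory
#'   only).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_cells_per_hemisphere = 600L,
                            ellipsoid_semi_axes = c(500, 200, 150),
                            midline_axis = 2L,
                            n_subjects = 3L,
                            conditions = c("spontaneous", "PT", "OMR",
                                           "Looming", "DF"),
                            n_frames = 300L,
                            structure_args = list(),
                            k_spatial = 80L, k_functional = 10L,
                            n_replicates = 5L,
                            max_diameter = 200, min_gap = 60,
                            n_surrogates = 200L,
                            n_gamma = 200L,
                            n_multilayer = 100L,
                            module_range = c(2, 25),
                            alpha = 0.05,
                            n_perm_consensus = 50L,
                            n_perm_mantel = 999L,
                            class_thresholds = c(0.1, 0.5),
                            seed = 1L,
                            out_dir = NULL) {
  if (length(conditions) == 0L)
    stop_mesoconn("conditions must be non-empty", class = "invalid_spec")
  if (!"spontaneous" %in% conditions)
    stop_mesoconn("conditions must include 'spontaneous'",
                  class = "invalid_spec")
  if (is.null(seed))
    stop_mesoconn("a master seed is required", class = "invalid_spec")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full mesoscale connectivity analysis on synthetic data
#'
#' Executes, in order: study simulation, parcellation, per-condition
#' functional network construction (global signal regression on
#' condition-concatenated traces, then restriction to condition frames),
#' phase-randomized surrogate networks, group averaging, resolution-sampled
#' hierarchical consensus modules with surrogate significance, hub metrics,
#' geometry and hemisphere-symmetry profiling, spontaneous-versus-stimulus
#' similarity (including Mantel tests), multilayer modules with node
#' flexibility, and the intersubject similarity report. Every stage draws
#' its seed deterministically from the master seed.
#'
#' @param config A [pipeline_config()].
#' @return An `analysis_report`: list with `stats` (named headline
#'   statistics), `parcellation`, `hierarchy`, `hubs`, `flexibility`,
#'   `significance`, `similarity`, `geometry`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 10L)

  ## 1. simulate -----------------------------------------------------------
  spec <- synthetic_brain_spec(
    n_cells_per_hemisphere = config$n_cells_per_hemisphere,
    ellipsoid_semi_axes = config$ellipsoid_semi_axes,
    midline_axis = config$midline_axis, seed = seeds[[1]])
  cells <- generate_cells(spec)
  structure_args <- utils::modifyList(
    list(cells = cells, conditions = config$conditions, seed = seeds[[2]]),
    config$structure_args)
  planted <- do.call(planted_structure, structure_args)
  dataset <- generate_study(spec, planted, n_subjects = config$n_subjects,
                            conditions = config$conditions,
                            n_frames = config$n_frames, seed = seeds[[3]])

  ## 2. parcellate ---------------------------------------------------------
  params <- parcellation_params(
    k_spatial = config$k_spatial, k_functional = config$k_functional,
    n_replicates = config$n_replicates,
    max_diameter = config$max_diameter, min_gap = config$min_gap,
    seed = seeds[[4]])
  parc <- run_parcellation(dataset, params)

  ## 3. per-subject, per-condition networks --------------------------------
  n_cond <- length(config$conditions)
  frames_of <- function(ci) (ci - 1L) * config$n_frames +
    seq_len(config$n_frames)
  subj_nets <- list()      # [[subject]][[condition]]
  subj_parcel_traces <- list()
  for (s in seq_along(dataset$recordings)) {
    concat <- do.call(cbind, lapply(config$conditions, function(cond)
      dataset$recordings[[s]][[cond]]$traces))
    resid <- global_signal_regression(concat)
    pt_all <- parcel_average_traces(resid, parc)
    subj_parcel_traces[[s]] <- pt_all
    nets <- lapply(seq_len(n_cond), function(ci)
      compute_fc(pt_all[, frames_of(ci), drop = FALSE],
                 coords = parc$parcel_centroids,
                 condition = config$conditions[[ci]],
                 subject_id = names(dataset$recordings)[[s]]))
    names(nets) <- config$conditions
    subj_nets[[s]] <- nets
  }
  names(subj_nets) <- names(dataset$recordings)

  group_nets <- lapply(config$conditions, function(cond)
    group_average(lapply(subj_nets, `[[`, cond)))
  names(group_nets) <- config$conditions
  A <- group_nets[["spontaneous"]]

  ## 4. surrogates ---------------------------------------------------------
  spont_frames <- frames_of(match("spontaneous", config$conditions))
  surr_seeds <- derive_seeds(seeds[[5]], length(subj_parcel_traces))
  surr_by_subj <- lapply(seq_along(subj_parcel_traces), function(s)
    phase_randomized_surrogates(
      subj_parcel_traces[[s]][, spont_frames, drop = FALSE],
      config$n_surrogates, seed = surr_seeds[[s]]))
  surrogate_group_fcs <- lapply(seq_len(config$n_surrogates), function(k)
    group_average(lapply(surr_by_subj, function(ss)
      compute_fc(ss[[k]]))))
  # mean Spearman similarity of each subject's FC with its surrogate FCs
  surr_sim <- mean(vapply(seq_along(subj_nets), function(s) {
    src <- upper_tri_vec(subj_nets[[s]][["spontaneous"]]$weights)
    mean(vapply(surr_by_subj[[s]], function(ss)
      stats::cor(src, upper_tri_vec(compute_fc(ss)$weights),
                 method = "spearman"), 1))
  }, 1))

  ## 5. hierarchical modules + significance --------------------------------
  bounds <- gamma_bounds(A, seed = seeds[[6]])
  gammas <- sample_gamma_values(A, config$n_gamma, bounds,
                                seed = seeds[[6]] + 1L)
  part_seeds <- derive_seeds(seeds[[6]] + 2L, config$n_gamma)
  ensemble <- lapply(seq_len(config$n_gamma), function(k)
    louvain_optimize(A, gammas[[k]], seed = part_seeds[[k]],
                     n_restarts = 1L))
  hier <- consensus_hierarchy(ensemble, alpha = config$alpha,
                              seed = seeds[[7]],
                              n_perm = config$n_perm_consensus,
                              A = A, gammas = gammas)
  signif <- modularity_significance(
    A, surrogate_group_fcs, hier$gamma_per_level, seed = seeds[[7]] + 1L)

  ## 6. hubs + geometry ----------------------------------------------------
  hubs <- hierarchy_participation(A, hier)
  part_strength_r <- suppressWarnings(
    stats::cor(hubs$mean, hubs$strength))
  geometry <- distance_profile(A,
                               class_thresholds = config$class_thresholds,
                               hemisphere = parc$parcel_hemisphere)
  hemi_r <- hemisphere_similarity(A, parc)

  ## 7. spontaneous vs stimulus --------------------------------------------
  stim <- setdiff(config$conditions, "spontaneous")
  cond_report <- similarity_report(group_nets,
                                   conditions = config$conditions)
  R <- cond_report$pairwise_r
  stim_idx <- match(stim, config$conditions)
  inter_stimulus_r <- if (length(stim) >= 2L)
    mean(R[stim_idx, stim_idx][upper.tri(diag(length(stim)))]) else NA_real_
  mantel_seeds <- derive_seeds(seeds[[8]], length(stim))
  mantel <- lapply(seq_along(stim), function(k)
    mantel_test(A, group_nets[[stim[[k]]]], n_perm = config$n_perm_mantel,
                seed = mantel_seeds[[k]]))
  names(mantel) <- stim

  ## 8. multilayer + flexibility -------------------------------------------
  ml_gammas <- sample_gamma_values(A, config$n_multilayer, bounds,
                                   seed = seeds[[9]])
  ml_omegas <- sample_omega_values(config$n_multilayer,
                                   seed = seeds[[9]] + 1L)
  ml <- multilayer_ensemble(group_nets, ml_gammas, ml_omegas,
                            seed = seeds[[9]] + 2L)
  flex <- flexibility_summary(ml$profiles,
                              module_range = config$module_range)
  flex_part_r <- flexibility_participation_correlation(flex, hubs)

  ## 9. intersubject similarity --------------------------------------------
  all_nets <- unlist(subj_nets, recursive = FALSE)
  subj_labels <- rep(names(subj_nets), each = n_cond)
  cond_labels <- rep(config$conditions, times = length(subj_nets))
  subj_report <- similarity_report(all_nets, subjects = subj_labels,
                                   conditions = cond_labels)

  stats <- list(
    n_parcels = parc$n_parcels,
    frac_parcels_all_subjects = parc$frac_parcels_all_subjects,
    hemisphere_r = hemi_r,
    hierarchy_depth = length(hier$levels),
    modularity_min_p_bonferroni = min(signif$p_bonferroni),
    participation_strength_r = part_strength_r,
    inter_stimulus_mean_r = inter_stimulus_r,
    mantel_min_r = min(vapply(mantel, `[[`, 1, "r")),
    mantel_max_p = max(vapply(mantel, `[[`, 1, "p")),
    flexibility_participation_r = flex_part_r,
    intersubject_spontaneous_r =
      subj_report$intersubject_spontaneous_mean,
    self_similarity_mean = subj_report$self_similarity_mean,
    intersubject_similarity_mean =
      subj_report$intersubject_similarity_mean,
    surrogate_similarity_mean = surr_sim)

  report <- base::structure(
    list(stats = stats, parcellation = parc, hierarchy = hier,
         hubs = hubs, flexibility = flex, significance = signif,
         mantel = mantel, similarity = list(conditions = cond_report,
                                            subjects = subj_report),
         geometry = geometry, group_networks = group_nets,
         config = config, seeds = seeds),
    class = "analysis_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_parcellation(parc, file.path(config$out_dir, "parcellation"))
    write_fc_network(A, file.path(config$out_dir, "fc_group_spontaneous"))
    write_hierarchy(hier, file.path(config$out_dir, "hierarchy.json"))
    jsonlite::write_json(stats,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report\n")
  for (nm in names(x$stats))
    cat(sprintf("  %-32s %s\n", nm,
                format(x$stats[[nm]], digits = 4)))
  invisible(x)
}
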