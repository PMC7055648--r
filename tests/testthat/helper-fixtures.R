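# Fixtures built in code at test time.

# Planted two-coarse / four-fine 64-node weight matrix: within-fine blocks
# strongest, within-coarse intermediate, between-coarse weakest, plus
# symmetric Gaussian noise. Fine modules 1-2 nest in coarse 1, 3-4 in
# coarse 2.
planted_hierarchy_matrix <- function(n = 64, within_fine = 0.8,
                                     within_coarse = 0.45, between = 0.1,
                                     noise_sd = 0.05, seed = 1) {
  stopifnot(n %% 4 == 0)
  fine <- rep(1:4, each = n / 4)
  coarse <- ifelse(fine <= 2, 1L, 2L)
  W <- matrix(between, n, n)
  W[outer(coarse, coarse, "==")] <- within_coarse
  W[outer(fine, fine, "==")] <- within_fine
  set.seed(seed)
  E <- matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
  W <- W + (E + t(E)) / 2
  diag(W) <- 0
  list(W = W, fine = fine, coarse = coarse)
}

# Small study with planted flexible nodes for multilayer tests: returns
# per-condition cell-level FC layers plus the flexible set.
flexible_study_layers <- function(n_per_hemi = 24, n_flexible = 8,
                                  n_frames = 400, seed = 1,
                                  conditions = c("spontaneous", "PT",
                                                 "OMR")) {
  spec <- synthetic_brain_spec(n_cells_per_hemisphere = n_per_hemi,
                               seed = seed)
  cells <- generate_cells(spec)
  set.seed(seed + 1)
  flex <- sort(sample(nrow(cells$positions), n_flexible))
  ps <- planted_structure(
    cells, n_coarse = 2, n_fine_per_coarse = 2,
    within_fine_corr = 0.7, within_coarse_corr = 0.35,
    between_corr = 0.05, decay_rate = 0, global_amp = 0,
    noise_sd = sqrt(1 - 0.7),
    flexible_cells = flex, conditions = conditions,
    condition_remap = stats::setNames(
      c(3L, 2L)[seq_len(length(conditions) - 1)],
      setdiff(conditions, "spontaneous")),
    subject_loading_sd = 0, seed = seed + 2)
  layers <- lapply(seq_along(conditions), function(ci) {
    rec <- generate_activity(cells, ps, n_frames = n_frames,
                             condition = conditions[[ci]],
                             seed = seed + 10 + ci)
    compute_fc(rec$traces, coords = cells$positions,
               condition = conditions[[ci]])
  })
  names(layers) <- conditions
  list(layers = layers, flexible = flex, structure = ps, cells = cells)
}

# Small multi-subject study for similarity / parcellation tests.
small_study <- function(n_per_hemi = 100, n_subjects = 3, n_frames = 200,
                        seed = 1,
                        conditions = c("spontaneous", "PT", "OMR")) {
  spec <- synthetic_brain_spec(n_cells_per_hemisphere = n_per_hemi,
                               seed = seed)
  generate_study(spec, structure = NULL, n_subjects = n_subjects,
                 conditions = conditions, n_frames = n_frames, seed = seed)
}
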