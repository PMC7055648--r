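test_that("participation evaluates closed forms and brute force", {
  # all positive links inside the node's own module
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  expect_equal(participation_coefficient(W, c(1, 1, 2, 2))[1], 0)

  # equal positive weight to each of 4 modules
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- W[2:5, 1] <- 0.3
  p <- participation_coefficient(W, c(1, 1, 2, 3, 4))
  expect_equal(p[1], 0.75)

  # brute-force evaluation on a random signed network
  set.seed(30)
  W <- rand_signed_matrix(20)
  labels <- sample(1:5, 20, replace = TRUE)
  p <- participation_coefficient(W, labels)
  for (i in c(1, 7, 13)) {
    wp <- pmax(W[i, ], 0); wp[i] <- 0
    k <- sum(wp)
    kappa <- tapply(wp, labels, sum)
    expect_equal(p[i], 1 - sum((kappa / k)^2))
  }
  # bound 1 - 1/C given C modules
  C <- length(unique(labels))
  expect_true(all(p <= 1 - 1 / C + 1e-12))
})

test_that("hierarchy participation averages levels and ranks connectors", {
  set.seed(31)
  W <- rand_signed_matrix(12)
  lv <- list(sample(1:2, 12, TRUE), sample(1:4, 12, TRUE))
  h <- hierarchy_participation(W, lv)
  expect_equal(h$mean, rowMeans(cbind(
    participation_coefficient(W, lv[[1]]),
    participation_coefficient(W, lv[[2]]))))
  h1 <- hierarchy_participation(W, lv[1])
  expect_equal(h1$mean, participation_coefficient(W, lv[[1]]))
  h2 <- hierarchy_participation(W, list(lv[[1]], lv[[1]]))
  expect_equal(h2$level_correlation[1, 2], 1)

  # planted connectors: nodes wired equally to all modules rank on top
  for (seed in 1:3) {
    set.seed(seed)
    n <- 24
    labels <- rep(1:4, each = 6)
    W <- matrix(0, n, n)
    W[outer(labels, labels, "==")] <- 0.8
    connectors <- c(3, 9, 15)
    W[connectors, ] <- 0.5
    W[, connectors] <- 0.5
    W <- W + (function(E) (E + t(E)) / 2)(matrix(rnorm(n * n, sd = 0.02),
                                                 n, n))
    diag(W) <- 0
    hp <- hierarchy_participation(W, list(labels))
    top <- order(hp$mean, decreasing = TRUE)[1:3]
    expect_setequal(top, connectors)
  }
})

test_that("absolute strength sums connection magnitudes", {
  expect_equal(absolute_strength(matrix(0, 4, 4)), rep(0, 4))
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- -0.5
  expect_equal(absolute_strength(W)[1], 1)
  set.seed(32)
  W <- rand_signed_matrix(10)
  expect_equal(absolute_strength(W), rowSums(abs(W)))
})

test_that("z-Rand follows its combinatorial definition", {
  # hand-counted components: X = Y, two balanced modules on 8 nodes
  x <- rep(1:2, each = 4)
  zr <- zrand_score(x, x)
  expect_equal(zr$components$W, 28)
  expect_equal(zr$components$W_X, 12)
  expect_equal(zr$components$W_Y, 12)
  expect_equal(zr$components$w_XY, 12)
  expect_gt(zr$z, 0)

  # invariant to relabeling, symmetric in arguments
  set.seed(33)
  a <- sample(1:3, 30, TRUE)
  b <- sample(1:4, 30, TRUE)
  expect_equal(zrand_score(a, b)$z,
               zrand_score(c(3, 1, 2)[a], b)$z)
  expect_equal(zrand_score(a, b)$z, zrand_score(b, a)$z)

  # closed-form sigma agrees with a permutation Monte-Carlo oracle
  sd_mc <- perm_sd_w(a, b, n_perm = 4000)
  expect_equal(zr_sigma <- zrand_score(a, b)$components$sigma_wXY,
               sd_mc, tolerance = 0.1)

  # null calibration: mean Z over independent random partitions is ~ 0
  zs <- vapply(1:400, function(i)
    zrand_score(sample(1:4, 50, TRUE), sample(1:4, 50, TRUE))$z, 1)
  expect_lt(abs(mean(zs)), 0.1)

  expect_error(zrand_score(1:8, rep(1:2, each = 4)),
               class = "undefined_variance")
  expect_error(zrand_score(rep(1, 8), rep(1:2, each = 4)),
               class = "undefined_variance")
})

test_that("distance profiles bin weights and classify connections", {
  # uniform-weight network: flat profile, single class
  n <- 16
  coords <- cbind(runif(n, 0, 100), runif(n, 0, 100), 0)
  W <- matrix(0.7, n, n); diag(W) <- 0
  gp <- distance_profile(W, coords = coords, bin_edges = c(0, 50, 150))
  nonempty <- !is.na(gp$mean_weight)
  expect_true(all(abs(gp$mean_weight[nonempty] - 0.7) < 1e-12))
  expect_true(all(abs(colSums(gp$class_proportions[, nonempty]) - 1) <
                    1e-12))
  expect_equal(unname(gp$class_proportions["strong_positive", nonempty]),
               rep(1, sum(nonempty)))

  # empty bins are NA, not zero
  far <- distance_profile(W, coords = coords,
                          bin_edges = c(0, 50, 150, 1e5, 2e5))
  expect_true(is.na(far$mean_weight[4]))
})

test_that("decay slope is recovered from generated distance-decaying data", {
  spec <- synthetic_brain_spec(n_cells_per_hemisphere = 150, seed = 40)
  cells <- generate_cells(spec)
  eps <- 1e-9
  ps <- planted_structure(cells, n_coarse = 2, n_fine_per_coarse = 1,
                          within_fine_corr = 0.8 + 2 * eps,
                          within_coarse_corr = 0.8 + eps,
                          between_corr = 0.8, decay_rate = 0.004,
                          global_amp = 0, noise_sd = sqrt(1 - 0.8),
                          subject_loading_sd = 0, connector_mix = 0,
                          seed = 40)
  rec <- generate_activity(cells, ps, n_frames = 1500, seed = 41)
  r <- cor(t(rec$traces)); diag(r) <- 0
  gp <- distance_profile(r, coords = cells$positions,
                         bin_edges = seq(0, 700, by = 70))
  mw <- gp$mean_abs_weight
  expect_true(all(diff(mw[!is.na(mw)]) <= 0.02))   # essentially decreasing
  slope <- decay_slope(gp, min_abs_weight = 0.08)
  expect_lt(abs(slope - (-0.004)) / 0.004, 0.3)
})

test_that("hemisphere similarity is exact for mirrored networks and null for noise", {
  # mirror-symmetric network built by construction
  P <- 6
  parc <- structure(list(
    parcel_hemisphere = rep(c("L", "R"), each = P),
    homotopic_partner = c((P + 1):(2 * P), 1:P)), class = "parcellation")
  set.seed(42)
  WL <- rand_signed_matrix(P)
  W <- matrix(0, 2 * P, 2 * P)
  W[1:P, 1:P] <- WL
  W[(P + 1):(2 * P), (P + 1):(2 * P)] <- WL
  expect_equal(hemisphere_similarity(W, parc), 1)

  rs <- vapply(1:100, function(i) {
    W2 <- W
    W2[(P + 1):(2 * P), (P + 1):(2 * P)] <- rand_signed_matrix(P)
    hemisphere_similarity(W2, parc)
  }, 1)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("Mantel test agrees with vegan and is calibrated under the null", {
  set.seed(43)
  A <- rand_signed_matrix(15)
  B <- A + (function(E) (E + t(E)) / 2)(matrix(rnorm(225, sd = 0.3),
                                               15, 15))
  diag(B) <- 0
  m <- mantel_test(A, B, n_perm = 499, seed = 9)

  # observed statistic cross-checked against the vegan implementation
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(A + 2), as.dist(B + 2), permutations = 99)
  expect_equal(m$r, unname(vg$statistic), tolerance = 1e-12)

  # self-comparison: r = 1, p at the permutation floor
  self <- mantel_test(A, A, n_perm = 999, seed = 10)
  expect_equal(self$r, 1)
  expect_equal(self$p, 0.001)

  # calibration under independence
  ps <- vapply(1:60, function(i) {
    X <- rand_signed_matrix(12)
    Y <- rand_signed_matrix(12)
    mantel_test(X, Y, n_perm = 199, seed = i)$p
  }, 1)
  expect_gt(mean(ps > 0.05), 0.85)
  expect_error(mantel_test(A, B, n_perm = 0), class = "invalid_argument")
})

test_that("similarity reports separate self from other subjects", {
  set.seed(44)
  nets <- lapply(1:4, function(i) fc_network(rand_signed_matrix(8)))
  rep1 <- similarity_report(list(nets[[1]], nets[[1]], nets[[1]]))
  expect_true(all(abs(rep1$pairwise_r - 1) < 1e-12))

  # generator round trip: shared structure, per-subject fingerprints
  for (seed in 1:2) {
    st <- small_study(n_per_hemi = 40, n_subjects = 3, n_frames = 250,
                      seed = seed, conditions = c("spontaneous", "PT",
                                                  "OMR"))
    nets <- list(); subj <- c(); cond <- c()
    for (s in names(st$recordings)) for (cn in st$conditions) {
      nets <- c(nets, list(compute_fc(st$recordings[[s]][[cn]]$traces)))
      subj <- c(subj, s); cond <- c(cond, cn)
    }
    rep2 <- similarity_report(nets, subjects = subj, conditions = cond)
    expect_gt(rep2$self_similarity_mean, rep2$intersubject_similarity_mean)
    expect_gt(rep2$intersubject_spontaneous_mean, 0)
  }
  expect_error(similarity_report(list(fc_network(diag(0, 3)),
                                      fc_network(diag(0, 4)))),
               class = "incompatible_networks")
})

test_that("flexibility-participation correlation behaves at its limits", {
  x <- runif(20)
  expect_equal(flexibility_participation_correlation(x, x), 1)
  set.seed(45)
  rs <- vapply(1:200, function(i)
    flexibility_participation_correlation(rnorm(30), rnorm(30)), 1)
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(flexibility_participation_correlation(rep(1, 5), runif(5)),
               class = "undefined_correlation")
})
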