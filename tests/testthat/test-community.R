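test_that("modularity matches its definition on closed forms and brute force", {
  set.seed(10)
  W <- rand_signed_matrix(6)
  gamma <- 0.1

  expect_equal(modularity_score(W, 1:6, gamma), 0)        # singletons
  expect_equal(modularity_score(W, rep(1, 6), gamma),     # one module
               sum(W) - 6 * 5 * gamma)

  for (k in 1:10) {
    labels <- sample(1:3, 6, replace = TRUE)
    expect_equal(modularity_score(W, labels, gamma),
                 naive_modularity(W, labels, gamma))
  }

  # invariances: relabeling; shifting weights and gamma together
  labels <- c(1, 1, 2, 2, 3, 3)
  expect_equal(modularity_score(W, labels, gamma),
               modularity_score(W, c(3, 3, 1, 1, 2, 2), gamma))
  expect_equal(modularity_score(W, labels, gamma),
               modularity_score(W + 0.3 - diag(0.3, 6), labels,
                                gamma + 0.3))

  expect_error(modularity_score(W, c(1, 1, 2, NA, 2, 2), gamma),
               class = "invalid_partition")
})

test_that("Louvain respects the trivial-partition limits", {
  set.seed(11)
  W <- rand_signed_matrix(10)
  off <- W[row(W) != col(W)]

  high <- louvain_optimize(W, max(off) + 0.01, seed = 1)
  expect_equal(high$n_modules, 10)
  expect_equal(high$q, 0)

  low <- louvain_optimize(W, min(off) - 0.01, seed = 1)
  expect_equal(low$n_modules, 1)

  # never worse than both trivial partitions
  for (k in 1:10) {
    W <- rand_signed_matrix(12)
    gamma <- runif(1, -0.5, 0.5)
    p <- louvain_optimize(W, gamma, seed = k, n_restarts = 3)
    expect_gte(p$q, 0)
  }
})

test_that("Louvain reaches the exhaustive optimum on small instances", {
  set.seed(12)
  for (k in 1:25) {
    W <- rand_signed_matrix(7)
    gamma <- runif(1, -0.4, 0.5)
    ref <- brute_force_max_q(W - gamma)
    p <- louvain_optimize(W, gamma, seed = k)
    expect_gte(p$q, 0.95 * ref$qmax)
  }
})

test_that("gamma bounds bracket the interesting resolutions", {
  set.seed(13)
  W <- rand_signed_matrix(12)
  W[1, 2] <- W[2, 1] <- 0.9
  W[abs(W) > 0.9] <- 0.85 * sign(W[abs(W) > 0.9])
  W[1, 2] <- W[2, 1] <- 0.9
  b <- gamma_bounds(W, seed = 2)
  expect_equal(unname(b[["gamma_max"]]), 0.9)
  expect_lt(b[["gamma_min"]], b[["gamma_max"]])

  # slightly above gamma_max: singletons
  for (k in 1:5) {
    W <- rand_signed_matrix(8)
    gm <- max(W[row(W) != col(W)])
    p <- louvain_optimize(W, gm + 1e-6, seed = k)
    expect_equal(p$n_modules, 8)
  }
  expect_error(gamma_bounds(matrix(1, 3, 3) - diag(1, 3)),
               class = "degenerate_bounds")
})

test_that("resolution sampling follows the admissible weight distribution", {
  set.seed(14)
  W <- rand_signed_matrix(20)
  b <- c(gamma_min = -0.2, gamma_max = 0.8)
  g <- sample_gamma_values(W, 1000, b, seed = 3)
  expect_true(all(g >= b[[1]] & g <= b[[2]]))
  expect_identical(g, sample_gamma_values(W, 1000, b, seed = 3))

  admissible <- W[row(W) != col(W)]
  admissible <- admissible[admissible >= b[[1]] & admissible <= b[[2]]]
  ks <- suppressWarnings(ks.test(g, admissible))
  expect_gt(ks$p.value, 0.01)

  expect_error(sample_gamma_values(W, 10, c(10, 11)),
               class = "sampling_error")
})

test_that("coassignment counts pair co-occurrences exactly", {
  p1 <- c(1, 1, 2, 2)
  C <- build_coassignment(list(p1, p1, p1))
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], 0)
  expect_equal(diag(C), rep(1, 4), ignore_attr = TRUE)

  C2 <- build_coassignment(list(c(1, 1, 2, 2), c(1, 2, 2, 1)))
  expect_equal(C2[1, 2], 0.5)

  set.seed(15)
  parts <- lapply(1:100, function(i) sample(1:4, 12, replace = TRUE))
  C3 <- build_coassignment(parts)
  brute <- matrix(0, 12, 12)
  for (p in parts) brute <- brute + outer(p, p, "==")
  expect_equal(C3, brute / 100, ignore_attr = TRUE)
})

test_that("consensus reproduces a unanimous two-module division", {
  p <- c(rep(1, 6), rep(2, 6))
  parts <- replicate(40, sample(10, 1) * 0 + p, simplify = FALSE)
  h <- consensus_hierarchy(parts, seed = 5, n_perm = 50)
  expect_equal(length(h$levels), 1)
  expect_equal(canon_labels(h$levels[[1]]$labels), canon_labels(p))
})

test_that("consensus hierarchy levels are nested refinements", {
  fix <- planted_hierarchy_matrix(n = 32, seed = 21)
  b <- gamma_bounds(fix$W, seed = 6)
  gammas <- sample_gamma_values(fix$W, 120, b, seed = 7)
  parts <- lapply(seq_along(gammas), function(k)
    louvain_optimize(fix$W, gammas[[k]], seed = k, n_restarts = 1))
  h <- consensus_hierarchy(parts, seed = 8, n_perm = 50, A = fix$W,
                           gammas = gammas)
  expect_gte(length(h$levels), 1)
  if (length(h$levels) > 1) {
    for (k in 2:length(h$levels)) {
      coarse <- h$levels[[k - 1]]$labels
      fine <- h$levels[[k]]$labels
      # refinement: every fine module lies inside one coarse module
      expect_true(all(tapply(coarse, fine,
                             function(v) length(unique(v))) == 1))
    }
  }
  # determinism
  h2 <- consensus_hierarchy(parts, seed = 8, n_perm = 50, A = fix$W,
                            gammas = gammas)
  expect_identical(lapply(h$levels, `[[`, "labels"),
                   lapply(h2$levels, `[[`, "labels"))
})

test_that("surrogate comparison yields valid permutation p-values", {
  fix <- planted_hierarchy_matrix(n = 24, seed = 31)
  set.seed(32)
  weak <- replicate(99, {
    E <- matrix(rnorm(24 * 24, sd = 0.05), 24, 24)
    W <- (E + t(E)) / 2
    diag(W) <- 0
    W
  }, simplify = FALSE)
  res <- suppressWarnings(
    modularity_significance(fix$W, weak, gammas = c(0.3), seed = 33))
  expect_equal(res$p, 0.01)              # no surrogate beats the planted net

  # the network included among its own surrogates bounds p from below
  res2 <- suppressWarnings(modularity_significance(
    fix$W, c(list(fix$W), weak[1:19]), gammas = c(0.3), seed = 34))
  expect_gte(res2$p, 1 / 21)
  expect_true(all(res2$p > 0 & res2$p <= 1))
})
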