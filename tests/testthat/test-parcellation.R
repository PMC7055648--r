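test_that("spatial k-means separates blobs and assigns by nearest centroid", {
  set.seed(50)
  blob1 <- matrix(rnorm(60, sd = 2), ncol = 3)
  blob2 <- matrix(rnorm(60, sd = 2), ncol = 3) + 100
  pts <- rbind(blob1, blob2)
  params <- parcellation_params(k_spatial = 2, k_functional = 1,
                                max_diameter = 50, min_gap = 10, seed = 1)
  sc <- spatial_kmeans_left(pts, params)
  expect_equal(length(unique(sc$assignment[1:20])), 1)
  expect_equal(length(unique(sc$assignment[21:40])), 1)
  expect_false(sc$assignment[1] == sc$assignment[21])

  # Voronoi property against a brute-force nearest-centroid check
  params2 <- parcellation_params(k_spatial = 7, k_functional = 2,
                                 max_diameter = 50, min_gap = 10, seed = 2)
  sc2 <- spatial_kmeans_left(pts, params2)
  d <- as.matrix(dist(rbind(pts, sc2$centroids)))[1:40, 41:47]
  expect_equal(sc2$assignment, unname(apply(d, 1, which.min)))

  expect_error(spatial_kmeans_left(pts[1:5, ],
                                   parcellation_params(k_spatial = 10,
                                                       k_functional = 2,
                                                       max_diameter = 5,
                                                       min_gap = 1)),
               class = "infeasible_clustering")
})

test_that("mirroring yields symmetric clusters and exact assignments", {
  spec <- synthetic_brain_spec(n_cells_per_hemisphere = 250, seed = 51)
  cells <- generate_cells(spec)
  L <- cells$positions[cells$hemisphere == "L", ]
  R <- cells$positions[cells$hemisphere == "R", ]
  params <- parcellation_params(k_spatial = 12, k_functional = 3,
                                max_diameter = 400, min_gap = 50, seed = 3)
  scL <- spatial_kmeans_left(L, params)
  sc <- mirror_assign(scL, R, midline_axis = spec$midline_axis)

  # mirrored population: left and right cluster sizes identical
  sizesL <- table(sc$assignment)
  sizesR <- table(sc$right_assignment - scL$k)
  expect_equal(as.integer(sizesL), as.integer(sizesR))

  # homotopic map is the L <-> R pairing
  expect_equal(sc$homotopic_map[1], scL$k + 1L)
  expect_equal(sc$homotopic_map[scL$k + 1L], 1L)

  # a cell exactly on a mirrored centroid joins that cluster
  probe <- sc$centroids[scL$k + 4L, , drop = FALSE]
  sc_probe <- mirror_assign(scL, probe, midline_axis = spec$midline_axis)
  expect_equal(sc_probe$right_assignment, scL$k + 4L)

  # brute-force nearest-centroid oracle
  dR <- as.matrix(dist(rbind(R, sc$centroids[-(1:scL$k), ])))[
    seq_len(nrow(R)), nrow(R) + seq_len(scL$k)]
  expect_equal(sc$right_assignment - scL$k,
               unname(apply(dR, 1, which.min)))

  expect_error(mirror_assign(scL, R[0, , drop = FALSE]),
               class = "degenerate_input")
})

test_that("global signal regression leaves orthogonal, idempotent residuals", {
  set.seed(52)
  traces <- matrix(rnorm(20 * 100), 20, 100) +
    outer(runif(20, 0.5, 2), sin(1:100 / 5))
  res <- global_signal_regression(traces)
  g <- colMeans(traces)
  expect_true(all(abs(res %*% (g - mean(g))) < 1e-8))

  # idempotent: the residual global mean is ~ 0, so a second pass is inert
  res2 <- global_signal_regression(res)
  expect_equal(res2, res, tolerance = 1e-8)

  # a trace equal to the global signal is fully explained
  traces[1, ] <- colMeans(traces[-1, ])   # row 1 now equals the global mean
  res3 <- global_signal_regression(traces)
  expect_lt(max(abs(res3[1, ])), 1e-8)

  expect_error(global_signal_regression(matrix(5, 3, 10)),
               class = "ill_posed_regression")
})

test_that("functional k-means recovers correlation blocks", {
  set.seed(53)
  blocks <- rep(1:3, times = c(5, 6, 7))
  C <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.9, 0.05))
  diag(C) <- 1
  C <- C + (function(E) (E + t(E)) / 2)(matrix(rnorm(18 * 18, sd = 0.01),
                                               18, 18))
  params <- parcellation_params(k_spatial = 18, k_functional = 3,
                                max_diameter = 100, min_gap = 10, seed = 4)
  labels <- functional_kmeans(C, params)
  expect_equal(canon_labels(labels), canon_labels(blocks))

  # duplicate rows always share a label
  C2 <- C
  C2[2, ] <- C2[1, ]
  labels2 <- functional_kmeans(C2, params)
  expect_equal(labels2[1], labels2[2])

  # invariance to a common positive affine transform of rows
  labels3 <- functional_kmeans(2.5 * C + 0.3, params)
  expect_equal(canon_labels(labels3), canon_labels(labels))

  expect_error(functional_kmeans(C[1:2, 1:2],
                                 parcellation_params(k_spatial = 18,
                                                     k_functional = 5,
                                                     max_diameter = 100,
                                                     min_gap = 10)),
               class = "infeasible_clustering")
})

test_that("spatial constraints split, respect gaps, and terminate", {
  params <- parcellation_params(k_spatial = 10, k_functional = 2,
                                max_diameter = 200, min_gap = 60, seed = 5)

  # compact functional cluster of diameter ~50: a single parcel
  set.seed(54)
  cent <- cbind(runif(6, 0, 30), runif(6, 0, 30), runif(6, 0, 30))
  out <- enforce_spatial_constraints(rep(1L, 6), cent, params)
  expect_length(out$groups, 1)

  # two groups 300 px apart: forced split
  cent2 <- rbind(cent, sweep(cent, 2, c(300, 0, 0), "+"))
  out2 <- enforce_spatial_constraints(rep(1L, 12), cent2, params)
  expect_length(out2$groups, 2)

  # randomized inputs: every output satisfies both constraints (brute force)
  for (seed in 1:5) {
    set.seed(seed)
    k <- 40
    cent <- cbind(runif(k, 0, 500), runif(k, -150, 150),
                  runif(k, 0, 120))
    flabels <- sample(1:4, k, replace = TRUE)
    out <- enforce_spatial_constraints(flabels, cent, params)
    for (g in out$groups)
      expect_lt(max(0, if (length(g) > 1)
        max(dist(cent[g, , drop = FALSE])) else 0), params$max_diameter)
    fl <- out$functional_of_parcel
    for (a in seq_along(out$groups)) for (b in seq_along(out$groups)) {
      if (a < b && fl[a] == fl[b]) {
        gap <- min(as.matrix(dist(rbind(
          cent[out$groups[[a]], , drop = FALSE],
          cent[out$groups[[b]], , drop = FALSE])))[
            seq_along(out$groups[[a]]),
            length(out$groups[[a]]) + seq_along(out$groups[[b]])])
        expect_gte(gap, params$min_gap)
      }
    }
    # all inputs are preserved
    expect_setequal(unlist(out$groups), seq_len(k))
  }
})

test_that("the full parcellation is symmetric, deterministic, and recovers planted modules", {
  st <- small_study(n_per_hemi = 150, n_subjects = 2, n_frames = 150,
                    seed = 60)
  params <- parcellation_params(k_spatial = 30, k_functional = 6,
                                n_replicates = 5, max_diameter = 250,
                                min_gap = 60, seed = 6)
  parc <- run_parcellation(st, params)

  # homotopic involution without fixed points
  partner <- parc$homotopic_partner
  expect_equal(partner[partner], seq_len(parc$n_parcels))
  expect_true(all(partner != seq_len(parc$n_parcels)))
  expect_true(all(parc$parcel_hemisphere[partner] !=
                    parc$parcel_hemisphere))

  # left cells land in left parcels
  hemi_cell <- st$populations[[1]]$hemisphere
  expect_true(all(parc$parcel_hemisphere[parc$parcel_of_cell[
    hemi_cell == "L"]] == "L"))

  # determinism
  parc2 <- run_parcellation(st, params)
  expect_identical(parc$parcel_of_cell, parc2$parcel_of_cell)

  # parcels align with planted fine modules better than chance
  zr <- zrand_score(parc$parcel_of_cell, st$structure$fine)
  expect_gt(zr$z, 2)
})
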