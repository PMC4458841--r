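test_that("atlas geometry is deterministic, disjoint and well-shaped", {
  a1 <- make_atlas(atlas_spec(c(20L, 30L, 12L)), seed = 1L)
  a2 <- make_atlas(atlas_spec(c(20L, 30L, 12L)), seed = 1L)
  expect_identical(a1$labels, a2$labels)

  counts <- table(a1$labels[a1$labels > 0])
  expect_setequal(as.integer(names(counts)), 1:6)

  # disjointness is structural: every non-background voxel has one label;
  # check EC/PRC do not touch (2-voxel corridor)
  ec <- ectopo:::.vox_coords(atlas_voxels(a1, "EC"), dim(a1$labels))
  prc <- ectopo:::.vox_coords(atlas_voxels(a1, "PRC"), dim(a1$labels))
  dmin <- min(apply(prc, 1, function(p)
    min(pmax(abs(ec[, 1] - p[1]), abs(ec[, 2] - p[2]),
             abs(ec[, 3] - p[3])))))
  expect_gte(dmin, 3)

  # EC and SUB elongated with enough slices, 3-11 voxels per slice
  for (roi in c("EC", "SUB")) {
    sl <- a1$slice_axes$L[[roi]]
    expect_gte(length(sl), 10L)
    per_slice <- vapply(sl, nrow, integer(1))
    expect_true(all(per_slice >= 3 & per_slice <= 11))
  }
})

test_that("atlas construction fails on a grid that cannot hold the regions", {
  expect_error(make_atlas(atlas_spec(c(8L, 8L, 8L))), "cannot be placed")
})

test_that("bilateral atlas mirrors the geometry in x", {
  ab <- make_atlas(atlas_spec(c(20L, 30L, 12L), bilateral = TRUE))
  d <- dim(ab$labels)
  expect_identical(d[1], 40L)
  mirrored <- ab$labels[d[1]:1, , ]
  expect_identical(ab$labels, mirrored)
  expect_setequal(unique(ab$hemisphere), c("L", "R"))
})

test_that("planted EC weights follow the logistic gradient rules", {
  at <- small_atlas()
  # flat logistic: all weights exactly 0.5, every label PRC by tie rule
  tr0 <- plant_topography(at, topography_spec(mixing_steepness = 0,
                                              end_slices = 5L))
  expect_true(all(tr0$ec$weight == 0.5))
  expect_true(all(tr0$ec$label == "PRC"))

  tr <- small_truth()
  expect_true(all(tr$ec$weight >= 0 & tr$ec$weight <= 1))
  # monotone along the gradient direction
  g <- tr$spec$gradient_direction
  proj <- as.matrix(tr$ec[, c("x", "y", "z")]) %*% g
  ord <- order(proj)
  expect_true(all(diff(tr$ec$weight[ord]) >= -1e-12))
  # centroid voxel (zero projection) sits at the logistic midpoint
  ctr_w <- tr$ec$weight[which.min(abs(proj - mean(proj)))]
  expect_lt(abs(ctr_w - 0.5), 0.2)
  # both labels occur and are roughly balanced (30-70%)
  frac <- mean(tr$ec$label == "PHC")
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.7)
})

test_that("a zero gradient vector is rejected", {
  expect_error(topography_spec(gradient_direction = c(0, 0, 0)), "nonzero")
})

test_that("subiculum end-coupling slices must not overlap", {
  at <- small_atlas()   # 16 subiculum slices
  expect_error(plant_topography(at, topography_spec(end_slices = 9L)),
               "overlap")
  tr <- plant_topography(at, topography_spec(end_slices = 5L))
  expect_identical(sum(tr$sub$prc_end & tr$sub$phc_end), 0L)
})

test_that("noiseless generation mixes latents exactly", {
  at <- small_atlas()
  tr <- plant_topography(at, topography_spec(end_slices = 5L,
                                             direct_pathway_weight = 0))
  ds <- simulate_subject(at, tr, signal_only_noise(), no_task(),
                         n_volumes = 60L, seed = 5L)
  Y <- ectopo:::.bold_matrix(ds$bold)
  # an EC voxel is the stated convex mixture of the two latents
  for (i in c(1L, nrow(tr$ec))) {
    v <- tr$ec$voxel[i]; w <- tr$ec$weight[i]
    mix <- (1 - w) * ds$latents$prc + w * ds$latents$phc
    expect_lt(max(abs(Y[, v] - mix)), 1e-8)
    expect_lt(abs(var(Y[, v]) - var(mix)), 1e-8)
  }
  # with w near 1 the series is an affine image of the PHC latent
  hi <- which.max(tr$ec$weight)
  whi <- tr$ec$weight[hi]
  r <- cor(Y[, tr$ec$voxel[hi]],
           (1 - whi) * ds$latents$prc + whi * ds$latents$phc)
  expect_equal(r, 1, tolerance = 1e-12)
})

test_that("simulation is reproducible and seed-sensitive", {
  at <- small_atlas(); tr <- small_truth()
  d1 <- simulate_subject(at, tr, n_volumes = 55L, seed = 9L)
  d2 <- simulate_subject(at, tr, n_volumes = 55L, seed = 9L)
  d3 <- simulate_subject(at, tr, n_volumes = 55L, seed = 10L)
  expect_identical(d1$bold, d2$bold)
  expect_false(identical(d1$bold, d3$bold))
})

test_that("runs shorter than 50 volumes are refused", {
  expect_error(simulate_subject(small_atlas(), small_truth(),
                                n_volumes = 49L, seed = 1L), "n_volumes")
})

test_that("planted spike counts match the binomial generator", {
  at <- make_atlas(atlas_spec(c(20L, 24L, 10L)))
  tr <- plant_topography(at, topography_spec(end_slices = 4L))
  # spike draws do not depend on the other noise components, so those are
  # zeroed to keep 200 full-length runs cheap
  ns <- noise_spec(spike_rate = 0.02, noise_sd = 0, drift_amplitude = 0,
                   motion_coupling = 0, wm_csf_leak = 0)
  n_cohorts <- 200L
  counts <- vapply(seq_len(n_cohorts), function(i) {
    ds <- simulate_subject(at, tr, ns, no_task(), n_volumes = 370L,
                           seed = 1000L + i)
    length(ds$spike_volumes)
  }, integer(1))
  # 99% interval for the mean of 200 Binomial(370, 0.02) draws
  m <- 370 * 0.02
  se <- sqrt(370 * 0.02 * 0.98 / n_cohorts)
  expect_gt(mean(counts), m - 2.576 * se)
  expect_lt(mean(counts), m + 2.576 * se)
})

test_that("cohorts share ground truth but differ across seeds", {
  at <- small_atlas(); tr <- small_truth()
  co <- simulate_cohort(3, at, tr, n_volumes = 55L, seed = 7L)
  expect_length(co$subjects, 3L)
  expect_identical(co$atlas, at)
  expect_false(identical(co$subjects[[1]]$bold, co$subjects[[2]]$bold))
  co2 <- simulate_cohort(2, at, tr, n_volumes = 55L, seed = 8L)
  expect_false(identical(co$subjects[[1]]$bold, co2$subjects[[1]]$bold))
  expect_identical(co$truth, co2$truth)
  expect_error(simulate_cohort(1, at, tr, seed = 1L), "at least 2")
})
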