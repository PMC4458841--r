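test_that("intensity spikes are flagged by percent deviation", {
  g <- c(100, 100, 103, 100)
  motion <- matrix(0, 4, 6)
  sp <- detect_spikes(g, motion)
  # 103 deviates by |103 - 100.75| / 100.75 * 100 = 2.23% > 1.3%
  expect_identical(sp$volume, 3L)
  expect_identical(sp$reason, "intensity")

  # constant series and zero motion: nothing flagged
  sp0 <- detect_spikes(rep(100, 4), motion)
  expect_identical(nrow(sp0), 0L)
})

test_that("motion spikes are flagged at the mm-per-TR threshold", {
  g <- rep(100, 10)
  motion <- matrix(0, 10, 6)
  motion[6:10, 1] <- 0.4      # 0.4 mm jump between volumes 5 and 6
  sp <- detect_spikes(g, motion)
  expect_identical(sp$volume, 6L)
  expect_identical(sp$reason, "motion")

  # 0.25 mm jump stays under the 0.3 mm threshold
  motion2 <- matrix(0, 10, 6)
  motion2[6:10, 1] <- 0.25
  expect_identical(nrow(detect_spikes(g, motion2)), 0L)

  # rotations convert at 65 mm: 0.3/65 rad jump is right at threshold,
  # 0.5/65 rad is above
  motion3 <- matrix(0, 10, 6)
  motion3[6:10, 4] <- 0.5 / 65
  expect_identical(detect_spikes(g, motion3)$volume, 6L)
})

test_that("spike detection is scale invariant and rejects a zero mean", {
  set.seed(2)
  g <- 100 + rnorm(50)
  g[25] <- 110
  motion <- matrix(cumsum(rnorm(300, sd = 0.02)), 50, 6)
  s1 <- detect_spikes(g, motion)
  s2 <- detect_spikes(7.3 * g, motion)
  expect_identical(s1$volume, s2$volume)
  expect_error(detect_spikes(rep(0, 4), matrix(0, 4, 6)), "zero")
})

test_that("gaussian smoothing has the right identity and impulse behavior", {
  arr <- array(rnorm(6 * 6 * 6 * 2), c(6, 6, 6, 2))
  expect_identical(gaussian_smooth(arr, 0, 0.8), arr)
  expect_error(gaussian_smooth(arr, -1, 0.8), "nonnegative")

  cst <- array(5, c(7, 7, 7))
  sm <- gaussian_smooth(cst, 1.5, 0.8)
  expect_lt(max(abs(sm - 5)), 1e-12)

  # unit impulse: peak equals the separable discrete kernel center weight
  imp <- array(0, c(11, 11, 11))
  imp[6, 6, 6] <- 1
  sm <- gaussian_smooth(imp, 1.5, 0.8)
  sigma <- 1.5 / (2 * sqrt(2 * log(2))) / 0.8
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  expect_equal(sm[6, 6, 6], k[r + 1]^3, tolerance = 1e-12)
  # away from the boundary (where kernels are not renormalized) the
  # smoothed impulse equals a brute-force separable convolution oracle
  brute <- array(0, c(11, 11, 11))
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r)
    brute[6 + dx, 6 + dy, 6 + dz] <-
      k[dx + r + 1] * k[dy + r + 1] * k[dz + r + 1]
  interior <- (1 + r):(11 - r)   # positions with full kernel windows
  expect_equal(sm[interior, interior, interior],
               brute[interior, interior, interior], tolerance = 1e-12)
})

test_that("design matrices have the expected columns and HRF peak", {
  motion <- matrix(rnorm(600), 100, 6)
  X <- build_task_design(NULL, motion, NULL, tr = 2, n_volumes = 100)
  expect_identical(ncol(X), 7L)   # 6 motion + intercept

  ev <- data.frame(onset = c(10, 50, 90, 130), duration = 3,
                   trial_type = rep(c("a", "b"), 2))
  sp <- detect_spikes(c(rep(100, 40), 110, rep(100, 59)),
                      matrix(0, 100, 6))
  sp2 <- rbind(sp, data.frame(volume = c(10L, 20L), reason = "motion"))
  attr(sp2, "n_volumes") <- 100L
  X <- build_task_design(ev, motion, sp2, tr = 2, n_volumes = 100)
  expect_identical(ncol(X), 2L + 6L + 3L + 1L)

  # a single event at t = 0: regressor peaks near the 5 s HRF peak
  ev1 <- data.frame(onset = 0, duration = 3, trial_type = "a")
  X1 <- build_task_design(ev1, matrix(rnorm(300), 50, 6), NULL,
                          tr = 2, n_volumes = 50)
  expect_lte(abs(which.max(X1[, "task_a"]) - (round(5 / 2) + 1)), 1)
})

test_that("task residualization is orthogonal, exact and idempotent", {
  set.seed(4)
  n <- 60
  motion <- matrix(rnorm(n * 6), n, 6)
  ev <- data.frame(onset = c(10, 60), duration = 4, trial_type = "a")
  X <- build_task_design(ev, motion, NULL, tr = 2, n_volumes = n)

  # bold that is exactly a linear combination of design columns
  Y <- X %*% matrix(rnorm(ncol(X) * 3), ncol(X), 3)
  R <- remove_task_effects(Y, X)
  expect_lt(max(abs(R)), 1e-8)

  # random bold: residuals orthogonal to every column
  Y <- matrix(rnorm(n * 5), n, 5)
  R <- remove_task_effects(Y, X)
  expect_lt(max(abs(crossprod(X, R))), 1e-6 * max(abs(Y)) * n)

  # idempotence
  R2 <- remove_task_effects(R, X)
  expect_lt(max(abs(R - R2)), 1e-8)

  # intercept-only design mean-centers
  R3 <- remove_task_effects(Y, matrix(1, n, 1))
  expect_equal(R3, sweep(Y, 2, colMeans(Y)), tolerance = 1e-12)

  # rank-deficient designs are reported with the offending column
  Xbad <- cbind(X, bad = X[, 1] + X[, 2])
  expect_error(remove_task_effects(Y, Xbad), "rank deficient")
})

test_that("ROI intensity thresholding removes only dropout voxels", {
  # 9 voxels at mean 100, one at 10: mean 91, sd 28.5 -> cut at 34.1
  Y <- rbind(c(rep(100, 9), 10), c(rep(100, 9), 10))
  kept <- threshold_roi_intensity(1:10, Y)
  expect_identical(kept, 1:9)

  # all equal: unchanged (sd 0)
  Yc <- matrix(100, 2, 5)
  expect_identical(threshold_roi_intensity(1:5, Yc), 1:5)

  # single-voxel ROI: unchanged
  expect_identical(threshold_roi_intensity(3L, Y), 3L)

  # a planted dropout voxel is reliably removed (its deviation dwarfs the
  # homogeneous spread even after it inflates the ROI SD)
  set.seed(8)
  for (i in 1:30) {
    base <- matrix(100 + rnorm(200), 4, 50)
    drop <- base; drop[, 7] <- drop[, 7] - 40
    kept <- threshold_roi_intensity(1:50, drop)
    expect_false(7L %in% kept)
  }
})

test_that("seed-border erosion respects the Chebyshev gap", {
  dims <- c(10L, 10L, 10L)
  seed <- array(FALSE, dims); targ <- array(FALSE, dims)
  targ[5, 5, 5] <- TRUE
  seed[4, 5, 5] <- TRUE     # adjacent
  seed[8, 5, 5] <- TRUE     # 3 voxels away
  out <- erode_seed_border(seed, targ, 2L)
  expect_false(out[4, 5, 5])
  expect_true(out[8, 5, 5])

  # gap 0 leaves disjoint masks unchanged
  expect_identical(erode_seed_border(seed, targ, 0L), seed)

  # far seed untouched at gap 2
  seed2 <- array(FALSE, dims); seed2[1, 1, 1] <- TRUE
  expect_identical(erode_seed_border(seed2, targ, 2L), seed2)

  # full erosion is an error
  seed3 <- array(FALSE, dims); seed3[4, 5, 5] <- TRUE
  expect_error(erode_seed_border(seed3, targ, 2L), "entire seed")
  # overlapping masks are rejected
  expect_error(erode_seed_border(targ, targ, 2L), "disjoint")
})
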