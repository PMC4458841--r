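zmap_for <- function(sections, values, subject = "s01", seed = "PRC") {
  structure(list(values = values, voxels = sections$voxel,
                 subject_id = subject, seed_id = seed,
                 band = c(0.01, 0.1), df_effective = 50L,
                 qc_zero_variance = integer(0)),
            class = "fisher_zmap")
}

test_that("longitudinal splits equalize voxel counts by whole slices", {
  # 10 slices x 4 voxels: clean 5/5 split
  co <- expand.grid(x = 1:2, z = 1:2, y = 1:10)[, c("x", "y", "z")]
  sp <- split_longitudinal(co)
  expect_identical(sum(sp$longitudinal == "anterior"), 20L)

  # anterior->posterior slice counts 5,5,5,9: the 10/14 cut beats 15/9
  co2 <- rbind(expand.grid(x = 1:5, y = 4, z = 1),
               expand.grid(x = 1:5, y = 3, z = 1),
               expand.grid(x = 1:5, y = 2, z = 1),
               expand.grid(x = 1:9, y = 1, z = 1))[, c("x", "y", "z")]
  sp2 <- split_longitudinal(co2)
  expect_identical(sum(sp2$longitudinal == "anterior"), 10L)
  expect_setequal(unique(sp2$slice_y[sp2$longitudinal == "anterior"]),
                  c(3L, 4L))

  # two slices split 1/1
  co3 <- expand.grid(x = 1:3, y = 1:2, z = 1)[, c("x", "y", "z")]
  sp3 <- split_longitudinal(co3)
  expect_identical(sum(sp3$longitudinal == "anterior"), 3L)
  expect_error(split_longitudinal(co3[co3$y == 1, ]), "single")
})

test_that("per-slice transverse bins are equal-count with lateral remainder", {
  # 5 voxels, 5 bins: one per bin, bin 1 most lateral (smallest x)
  co <- data.frame(x = c(3, 1, 5, 2, 4), y = 1, z = 1)
  sp <- split_transverse_per_slice(co, 5L)
  expect_identical(sp$transverse_bin[order(co$x)], 1:5)

  # 7 voxels, 2 bins: 4 lateral / 3 medial
  co2 <- data.frame(x = 1:7, y = 1, z = 1)
  sp2 <- split_transverse_per_slice(co2, 2L)
  expect_identical(as.integer(table(sp2$transverse_bin)), c(4L, 3L))
  expect_true(all(sp2$transverse_bin[co2$x <= 4] == 1L))

  # fewer voxels than bins errors with the slice named
  co3 <- data.frame(x = 1:4, y = 3, z = 1)
  expect_error(split_transverse_per_slice(co3, 5L), "y = 3")

  # the transverse axis follows the slice principal axis, not raw x:
  # a diagonal slice is ordered along its own elongation
  co4 <- data.frame(x = c(1, 2, 3, 4), y = 1, z = c(1, 2, 3, 4))
  sp4 <- split_transverse_per_slice(co4, 2L)
  expect_identical(sp4$transverse_rank, 1:4)
})

test_that("section assignment partitions the ROI exactly once", {
  at <- small_atlas()
  for (roi in c("EC", "SUB")) {
    sec <- section_assignment(at, roi)
    expect_setequal(sec$voxel, atlas_voxels(at, roi))
    expect_false(any(is.na(sec$longitudinal)))
    expect_false(any(is.na(sec$transverse_half)))
    expect_false(any(is.na(sec$transverse_quintile)))
    # halves differ by at most one voxel within each slice
    for (y in unique(sec$slice_y)) {
      tb <- table(sec$transverse_half[sec$slice_y == y])
      expect_lte(abs(tb[1] - tb[2]), 1)
    }
  }
})

test_that("section means aggregate cells correctly", {
  at <- small_atlas()
  sec <- section_assignment(at, "EC")
  cm <- section_means(zmap_for(sec, rep(2.5, nrow(sec))), sec)
  expect_true(all(cm$value == 2.5))
  expect_identical(nrow(cm), 4L)

  vals <- ifelse(sec$longitudinal == "anterior", 1, -1)
  cm2 <- section_means(zmap_for(sec, vals), sec)
  expect_true(all(cm2$value[cm2$longitudinal == "anterior"] == 1))
  expect_true(all(cm2$value[cm2$longitudinal == "posterior"] == -1))
})

test_that("the 2x2x2 ANOVA agrees with the aov sums-of-squares oracle", {
  for (s in 1:20) {
    tab <- random_cell_table(n_subjects = 15, seed = s)
    mine <- rm_anova_2x2x2(tab)
    oracle <- aov_oracle_F(tab)
    for (i in seq_len(nrow(mine))) {
      nm <- gsub(" ", "", names(oracle))
      key <- mine$effect[i]
      expect_equal(mine$F[i], unname(oracle[nm == key]), tolerance = 1e-8,
                   label = paste("effect", key, "seed", s))
    }
  }
})

test_that("ANOVA effects equal squared paired t and handle degenerate data", {
  tab <- random_cell_table(n_subjects = 12, seed = 99)
  res <- rm_anova_2x2x2(tab)
  # seed main effect equals squared paired t of seed means
  ag <- aggregate(value ~ subject + seed, tab, mean)
  a <- ag$value[ag$seed == "PHC"]; b <- ag$value[ag$seed == "PRC"]
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(res$F[res$effect == "seed"], unname(tt$statistic)^2,
               tolerance = 1e-10)

  # purely additive seed and longitudinal effects (dyadic values, so the
  # contrast cancels exactly in floating point) -> F = 0, p = 1
  tab0 <- random_cell_table(n_subjects = 6, seed = 1)
  set.seed(2)
  se <- matrix(sample(-8:8, 12) / 4, 6, 2,
               dimnames = list(sprintf("s%02d", 1:6), c("PRC", "PHC")))
  le <- matrix(sample(-8:8, 12) / 8, 6, 2,
               dimnames = list(sprintf("s%02d", 1:6),
                               c("anterior", "posterior")))
  tab0$value <- se[cbind(tab0$subject, tab0$seed)] +
    le[cbind(tab0$subject, tab0$longitudinal)]
  res0 <- rm_anova_2x2x2(tab0)
  expect_equal(res0$F[res0$effect == "seed:longitudinal"], 0,
               tolerance = 1e-16)
  expect_equal(res0$p[res0$effect == "seed:longitudinal"], 1,
               tolerance = 1e-12)

  # incomplete cells are reported
  expect_error(rm_anova_2x2x2(tab[-1, ]), "incomplete")
})

test_that("a planted seed-by-longitudinal crossover is detected with power", {
  set.seed(31)
  nsim <- 200
  hits <- vapply(seq_len(nsim), function(i) {
    tab <- expand.grid(subject = sprintf("s%02d", 1:15),
                       seed = c("PRC", "PHC"),
                       longitudinal = c("anterior", "posterior"),
                       transverse = c("lateral", "medial"),
                       stringsAsFactors = FALSE)
    eff <- ifelse((tab$seed == "PRC") == (tab$longitudinal == "anterior"),
                  0.2, -0.2)   # crossover of total range 0.4
    tab$value <- eff + rnorm(nrow(tab), sd = 0.1)
    res <- rm_anova_2x2x2(tab)
    res$p[res$effect == "seed:longitudinal"] < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("paired follow-ups match hand computation and are antisymmetric", {
  tab <- data.frame(subject = rep(c("a", "b", "c"), 2),
                    seed = rep(c("PRC", "PHC"), each = 3),
                    longitudinal = "anterior", transverse = "lateral",
                    value = c(1.1, 2.2, 3.3, 1.0, 2.0, 3.0))
  # differences 0.1, 0.2, 0.3 -> t = 0.2 / (0.1 / sqrt(3)) = 3.464
  r <- paired_followup(tab, list(seed = "PRC"), list(seed = "PHC"))
  expect_equal(r$t, 3.464102, tolerance = 1e-6)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)
  r2 <- paired_followup(tab, list(seed = "PHC"), list(seed = "PRC"))
  expect_equal(r2$t, -r$t, tolerance = 1e-12)
  expect_equal(r2$p, r$p, tolerance = 1e-12)
  # identical cells give t = 0, p = 1
  r3 <- paired_followup(tab, list(seed = "PRC"), list(seed = "PRC"))
  expect_true(is.nan(r3$t) || r3$t == 0 || r3$p == 1)
})

test_that("slice profiles are consistent with section means", {
  at <- small_atlas()
  sec <- section_assignment(at, "EC")
  set.seed(32)
  maps <- list(PRC = lapply(1:4, function(i)
    zmap_for(sec, rnorm(nrow(sec)), subject = paste0("s", i))))
  prof <- slice_profiles(maps, sec, "longitudinal")
  y0 <- sort(unique(sec$slice_y))[1]
  manual <- mean(vapply(maps$PRC, function(m)
    mean(m$values[sec$slice_y == y0]), numeric(1)))
  expect_equal(prof$mean[prof$position == y0], manual, tolerance = 1e-12)

  # constant maps give a flat profile; planted monotone gradient shows
  # a monotone transverse profile
  mapsc <- list(PRC = lapply(1:3, function(i) zmap_for(sec, rep(1, nrow(sec)))))
  pc <- slice_profiles(mapsc, sec, "transverse")
  expect_true(all(abs(pc$mean - 1) < 1e-12))
  grad <- list(PRC = lapply(1:3, function(i)
    zmap_for(sec, sec$transverse_quintile * 0.5)))
  pg <- slice_profiles(grad, sec, "transverse")
  expect_true(all(diff(pg$mean) > 0))
})

test_that("end-slice contrasts reduce to the whole-ROI contrast at k = all", {
  at <- small_atlas()
  sec <- section_assignment(at, "SUB", quintiles = FALSE)
  n_slices <- length(unique(sec$slice_y))
  set.seed(33)
  maps_a <- lapply(1:5, function(i) zmap_for(sec, rnorm(nrow(sec))))
  maps_b <- lapply(1:5, function(i) zmap_for(sec, rnorm(nrow(sec))))
  full <- end_slices_contrast(maps_a, maps_b, sec, k = n_slices)
  a <- vapply(maps_a, function(m) mean(m$values), numeric(1))
  b <- vapply(maps_b, function(m) mean(m$values), numeric(1))
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(full$t, unname(ref$statistic), tolerance = 1e-10)
  expect_identical(end_slices_contrast(maps_a, maps_a, sec, k = 3)$t, 0)
  expect_error(end_slices_contrast(maps_a, maps_b, sec, k = n_slices + 1),
               "fewer")
})

test_that("planted anterior end coupling is detected with power", {
  at <- small_atlas()
  sec <- section_assignment(at, "SUB", quintiles = FALSE)
  ys <- sort(unique(sec$slice_y))
  ant8 <- tail(ys, 8)
  set.seed(34)
  hits <- vapply(seq_len(200), function(i) {
    maps_a <- lapply(1:15, function(j)
      zmap_for(sec, 0.3 * (sec$slice_y %in% ant8) +
                 rnorm(nrow(sec), sd = 0.1)))
    maps_b <- lapply(1:15, function(j)
      zmap_for(sec, rnorm(nrow(sec), sd = 0.1)))
    end_slices_contrast(maps_a, maps_b, sec, k = 8)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("delta interaction isolates differing longitudinal profiles", {
  # equal difference profiles -> F = 0
  base <- expand.grid(subject = sprintf("s%02d", 1:10),
                      seed = c("alEC", "pmEC"),
                      longitudinal = c("anterior", "posterior"),
                      stringsAsFactors = FALSE)
  base$value <- ifelse(base$seed == "alEC", 0.4, 0.1)
  ctx <- base; ctx$seed <- ifelse(ctx$seed == "alEC", "PRC", "PHC")
  r0 <- delta_interaction(base, ctx)
  expect_equal(r0$F, 0, tolerance = 1e-20)

  # identity with the squared paired t of the difference of differences
  set.seed(35)
  base$value <- rnorm(nrow(base)); ctx$value <- rnorm(nrow(ctx))
  r <- delta_interaction(base, ctx)
  dd <- vapply(sprintf("s%02d", 1:10), function(s) {
    g <- function(tab, seed, lng)
      tab$value[tab$subject == s & tab$seed == seed &
                  tab$longitudinal == lng]
    (g(base, "alEC", "anterior") - g(base, "pmEC", "anterior") -
       (g(base, "alEC", "posterior") - g(base, "pmEC", "posterior"))) -
      (g(ctx, "PRC", "anterior") - g(ctx, "PHC", "anterior") -
         (g(ctx, "PRC", "posterior") - g(ctx, "PHC", "posterior")))
  }, numeric(1))
  tt <- mean(dd) / (sd(dd) / sqrt(10))
  expect_equal(r$F, tt^2, tolerance = 1e-10)

  # power: ctx pair slopes 0.3 along the long axis, EC pair flat
  set.seed(36)
  hits <- vapply(seq_len(200), function(i) {
    b <- base; c2 <- ctx
    b$value <- rnorm(nrow(b), sd = 0.1)
    c2$value <- ifelse(c2$seed == "PRC" & c2$longitudinal == "anterior",
                       0.3, 0) + rnorm(nrow(c2), sd = 0.1)
    delta_interaction(b, c2)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("statistics are invariant to subject ordering", {
  tab <- random_cell_table(n_subjects = 8, seed = 41)
  res1 <- rm_anova_2x2x2(tab)
  res2 <- rm_anova_2x2x2(tab[rev(seq_len(nrow(tab))), ])
  expect_equal(res1$F, res2$F, tolerance = 1e-10)
})
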