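# Shared small fixtures, built once per test session.

small_atlas <- function() {
  if (is.null(.fixture_env$atlas))
    .fixture_env$atlas <- make_atlas(atlas_spec(c(20L, 30L, 12L)))
  .fixture_env$atlas
}

small_truth <- function() {
  if (is.null(.fixture_env$truth))
    .fixture_env$truth <- plant_topography(small_atlas(),
                                           topography_spec(end_slices = 5L))
  .fixture_env$truth
}

# a quiet noise spec: only latent signals, no artifacts
signal_only_noise <- function(noise_sd = 0) {
  noise_spec(ar1_coefficient = 0, latent_signal_sd = 1, noise_sd = noise_sd,
             drift_amplitude = 0, motion_coupling = 0, spike_rate = 0,
             wm_csf_leak = 0, baseline = 0)
}

no_task <- function() task_spec(amplitudes = c(0, 0))

# a tiny analyzed cohort reused by several group-level tests
small_first_level <- function() {
  if (is.null(.fixture_env$fl))
    .fixture_env$fl <- run_first_level(6, small_atlas(), small_truth(),
                                       n_volumes = 60L, seed = 7L)
  .fixture_env$fl
}

# random cell-means table for ANOVA tests
random_cell_table <- function(n_subjects = 15, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(subject = sprintf("s%02d", seq_len(n_subjects)),
                      seed = c("PRC", "PHC"),
                      longitudinal = c("anterior", "posterior"),
                      transverse = c("lateral", "medial"),
                      stringsAsFactors = FALSE)
  grid$value <- rnorm(nrow(grid))
  grid
}

# independent within-subject ANOVA oracle via the full aov() stratum
# decomposition
aov_oracle_F <- function(tab) {
  tab$subject <- factor(tab$subject)
  tab$seed <- factor(tab$seed)
  tab$longitudinal <- factor(tab$longitudinal)
  tab$transverse <- factor(tab$transverse)
  fit <- stats::aov(value ~ seed * longitudinal * transverse +
                      Error(subject / (seed * longitudinal * transverse)),
                    data = tab)
  sm <- summary(fit)
  out <- c()
  for (stratum in sm) {
    st <- stratum[[1]]
    rn <- trimws(rownames(st))
    for (i in seq_along(rn)) {
      if (rn[i] != "Residuals")
        out[rn[i]] <- st[i, "F value"]
    }
  }
  out
}

pref_df <- function(voxels, labels, subject) {
  structure(data.frame(voxel = as.integer(voxels), label = labels,
                       magnitude = 1),
            subject_id = subject,
            class = c("preference_map", "data.frame"))
}

# a small common-space sample set over a 6x5x2 grid slab
toy_samples <- function(label_fn, n_subjects = 4, dims = c(6L, 5L, 2L)) {
  vox <- seq_len(prod(dims))
  co <- ectopo:::.vox_coords(vox, dims)
  maps <- lapply(seq_len(n_subjects), function(s)
    pref_df(vox, label_fn(co, s), sprintf("s%02d", s)))
  assemble_samples(maps, dims)
}

.fixture_env <- new.env(parent = emptyenv())
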