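#' Noise and artifact specification for synthetic BOLD
#'
#' Amplitudes are in arbitrary BOLD signal units on top of a mean
#' intensity of `baseline`; latent connectivity signals have SD
#' `latent_signal_sd` in the same units.
#'
#' @param ar1_coefficient Temporal autocorrelation of the voxelwise noise,
#'   in `[0, 1)`.
#' @param latent_signal_sd SD of each band-limited latent signal.
#' @param noise_sd Marginal SD of the AR(1) voxel noise.
#' @param drift_amplitude Typical amplitude of slow per-voxel drift over a
#'   run (linear plus half-cycle cosine components).
#' @param motion_coupling Signal change per mm of framewise displacement
#'   (per-voxel loadings drawn uniformly in `[0, motion_coupling]`).
#' @param spike_rate Probability per volume of a global intensity spike.
#' @param spike_magnitude Minimum size of a spike as percent of the mean
#'   intensity.
#' @param wm_csf_leak Amplitude with which WM and CSF compartment signals
#'   leak into every voxel (the global physiological confound).
#' @param baseline Mean image intensity.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(ar1_coefficient = 0.3, latent_signal_sd = 1,
                       noise_sd = 1, drift_amplitude = 2,
                       motion_coupling = 1, spike_rate = 0.01,
                       spike_magnitude = 3, wm_csf_leak = 0.3,
                       baseline = 100) {
  if (ar1_coefficient < 0 || ar1_coefficient >= 1)
    stop("ar1_coefficient must be in [0, 1)", call. = FALSE)
  amps <- c(latent_signal_sd, noise_sd, drift_amplitude, motion_coupling,
            spike_rate, spike_magnitude, wm_csf_leak, baseline)
  if (any(!is.finite(amps)) || any(amps < 0))
    stop("all noise amplitudes must be finite and nonnegative", call. = FALSE)
  structure(list(ar1_coefficient = ar1_coefficient,
                 latent_signal_sd = latent_signal_sd, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 motion_coupling = motion_coupling, spike_rate = spike_rate,
                 spike_magnitude = spike_magnitude,
                 wm_csf_leak = wm_csf_leak, baseline = baseline),
            class = "noise_spec")
}

#' Task specification for synthetic runs
#'
#' Either pass an explicit event table (columns `onset`, `duration`,
#' `trial_type`, all onsets in seconds) used verbatim for every subject,
#' or leave `events = NULL` to have each simulated subject draw its own
#' event onsets (uniformly over the run) with the stated condition set.
#'
#' @param conditions Character vector of condition names.
#' @param n_events Events per condition when onsets are drawn.
#' @param duration Event duration in seconds.
#' @param amplitudes Response amplitude per condition, signal units.
#' @param events Optional explicit event data frame.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(conditions = c("objects", "scenes"), n_events = 8L,
                      duration = 3, amplitudes = c(0.5, 0.5),
                      events = NULL) {
  if (!is.null(events)) {
    need <- c("onset", "duration", "trial_type")
    if (!all(need %in% names(events)))
      stop("events needs columns onset, duration, trial_type", call. = FALSE)
    if (any(events$onset < 0)) stop("onsets must be nonnegative", call. = FALSE)
    if (any(events$duration <= 0)) stop("durations must be > 0", call. = FALSE)
    conditions <- unique(as.character(events$trial_type))
  }
  if (length(amplitudes) == 1L)
    amplitudes <- rep(amplitudes, length(conditions))
  if (length(amplitudes) != length(conditions))
    stop("one amplitude per condition required", call. = FALSE)
  names(amplitudes) <- conditions
  structure(list(conditions = conditions, n_events = as.integer(n_events),
                 duration = duration, amplitudes = amplitudes,
                 events = events),
            class = "task_spec")
}

#' Canonical double-gamma haemodynamic response function
#'
#' The standard two-gamma HRF (response peak 5 s, undershoot peak 15 s,
#' peak-to-undershoot ratio 6), evaluated at times `t` in seconds.
#'
#' @param t Numeric vector of times (s).
#' @return HRF values, peak-normalized to 1.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h / max(stats::dgamma((0:1000) / 100, shape = 6, rate = 1) -
            stats::dgamma((0:1000) / 100, shape = 16, rate = 1) / 6)
}

# HRF-convolved regressor for one condition, sampled at volume times.
.task_regressor <- function(onsets, durations, tr, n_volumes, dt = 0.1) {
  run_len <- tr * n_volumes
  nfine <- ceiling(run_len / dt) + 1L
  box <- numeric(nfine)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- min(nfine, ceiling((onsets[i] + durations[i]) / dt))
    if (a <= nfine) box[a:b] <- 1
  }
  hrf <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(nfine)] * dt
  conv[pmin(nfine, round((0:(n_volumes - 1)) * tr / dt) + 1L)]
}

# Band-limited latent signal: low-pass filtered white noise, re-centered
# and rescaled to the requested SD.
.latent_signal <- function(n, tr, sd_target, cutoff = 0.1) {
  x <- .lowpass(rnorm(n), cutoff, tr)
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0 && sd_target > 0) x * (sd_target / s) else x * 0
}

#' Simulate one subject's 4-D BOLD dataset
#'
#' Generates a run with the planted connectivity topography: PRC and PHC
#' regions carry distinct band-limited latent signals; each EC voxel mixes
#' them according to its ground-truth weight `w`; subiculum voxels mix
#' anterior-lateral-EC-like and posterior-medial-EC-like signals along the
#' transverse axis, with direct (non-EC-relayed) seed coupling at the
#' longitudinal ends; WM and CSF compartments carry confound signals that
#' also leak globally; task events add HRF-convolved responses; AR(1)
#' noise, slow drift, motion-coupled fluctuations and global intensity
#' spikes complete the data.  Fully reproducible given `seed`.
#'
#' @param atlas A `labeled_atlas`.
#' @param truth A `ground_truth` from [plant_topography()].
#' @param noise A [noise_spec()].
#' @param task A [task_spec()].
#' @param tr Repetition time, seconds (default 2).
#' @param n_volumes Number of volumes (default 370); fewer than 50 is
#'   refused because the band-pass filter and correlation statistics are
#'   not meaningful on shorter runs.
#' @param subject_id Character id stored with the dataset.
#' @param seed Integer RNG seed.
#' @return An object of class `subject_dataset` with fields `bold`
#'   (4-D array), `tr`, `n_volumes`, `motion` (t x 6: translations mm,
#'   rotations rad), `events`, `subject_id`, `rng_seed`,
#'   `spike_volumes` (the planted spike volume indices, 1-based) and
#'   `latents` (the generating latent series, kept for validation).
#' @export
simulate_subject <- function(atlas, truth, noise = noise_spec(),
                             task = task_spec(), tr = 2, n_volumes = 370L,
                             subject_id = "sub-01", seed = 1L) {
  stopifnot(inherits(atlas, "labeled_atlas"), inherits(truth, "ground_truth"))
  n_volumes <- as.integer(n_volumes)
  if (n_volumes < 50L)
    stop("n_volumes < 50: filters and correlation statistics are not ",
         "defined at such short runs", call. = FALSE)
  set.seed(as.integer(seed))
  dims <- dim(atlas$labels)
  nvox <- prod(dims)
  nt <- n_volumes
  topo <- truth$spec

  # --- latent signals -----------------------------------------------------
  lsd <- noise$latent_signal_sd
  l_prc  <- .latent_signal(nt, tr, lsd)   # shared PRC signal (relayed to EC)
  l_phc  <- .latent_signal(nt, tr, lsd)
  l_prcp <- .latent_signal(nt, tr, lsd)   # private components (direct
  l_phcp <- .latent_signal(nt, tr, lsd)   # subiculum pathway only)
  l_wm   <- .latent_signal(nt, tr, lsd)
  l_csf  <- .latent_signal(nt, tr, lsd)

  gam <- topo$direct_pathway_weight
  s_prc <- (l_prc + gam * l_prcp) / sqrt(1 + gam^2)
  s_phc <- (l_phc + gam * l_phcp) / sqrt(1 + gam^2)

  w <- truth$ec$weight
  al <- w <= 0.5
  w_al <- if (any(al)) mean(w[al]) else 0.5
  w_pm <- if (any(!al)) mean(w[!al]) else 0.5
  s_alec <- (1 - w_al) * l_prc + w_al * l_phc
  s_pmec <- (1 - w_pm) * l_prc + w_pm * l_phc

  # --- motion -------------------------------------------------------------
  steps <- cbind(matrix(rnorm(nt * 3, sd = 0.02), nt, 3),
                 matrix(rnorm(nt * 3, sd = 4e-4), nt, 3))
  jump <- runif(nt) < 0.01
  if (any(jump)) {
    ax <- sample.int(3L, sum(jump), replace = TRUE)
    steps[cbind(which(jump), ax)] <- steps[cbind(which(jump), ax)] +
      0.45 * sample(c(-1, 1), sum(jump), replace = TRUE)
  }
  steps[1, ] <- 0
  motion <- apply(steps, 2, cumsum)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  fd <- c(0, sqrt(rowSums(diff(motion[, 1:3, drop = FALSE])^2)))

  # --- events -------------------------------------------------------------
  if (is.null(task$events)) {
    run_len <- nt * tr
    ev <- do.call(rbind, lapply(task$conditions, function(cn) {
      data.frame(onset = sort(runif(task$n_events, 0,
                                    max(1, run_len - task$duration - 20))),
                 duration = task$duration, trial_type = cn)
    }))
  } else ev <- task$events

  # --- assemble the t x V signal matrix -----------------------------------
  if (noise$noise_sd > 0) {
    M <- matrix(rnorm(nt * nvox, sd = noise$noise_sd *
                        sqrt(1 - noise$ar1_coefficient^2)), nt, nvox)
    phi <- noise$ar1_coefficient
    if (phi > 0)  # AR(1) recursion, vectorized across voxels
      for (t in 2:nt) M[t, ] <- M[t, ] + phi * M[t - 1L, ]
  } else {
    M <- matrix(0, nt, nvox)
  }

  lab <- as.integer(atlas$labels)
  add_signal <- function(idx, series) {
    if (length(idx)) M[, idx] <<- M[, idx] + series
  }
  add_signal(which(lab == REGION_CODES[["PRC"]]), s_prc)
  add_signal(which(lab == REGION_CODES[["PHC"]]), s_phc)
  add_signal(which(lab == REGION_CODES[["WM"]]), l_wm)
  add_signal(which(lab == REGION_CODES[["CSF"]]), l_csf)

  # EC: convex mixture of the two relayed seed signals
  ec_sig <- outer(l_prc, 1 - w) + outer(l_phc, w)
  M[, truth$ec$voxel] <- M[, truth$ec$voxel] + ec_sig

  # SUB: transverse mixture of EC-subregion signals + direct end coupling
  ws <- truth$sub$weight
  sub_sig <- outer(s_alec, 1 - ws) + outer(s_pmec, ws)
  ec_cp <- topo$end_coupling
  if (ec_cp > 0) {
    if (any(truth$sub$prc_end))
      sub_sig[, truth$sub$prc_end] <- sub_sig[, truth$sub$prc_end] +
        ec_cp * l_prcp
    if (any(truth$sub$phc_end))
      sub_sig[, truth$sub$phc_end] <- sub_sig[, truth$sub$phc_end] +
        ec_cp * l_phcp
  }
  M[, truth$sub$voxel] <- M[, truth$sub$voxel] + sub_sig

  # global confound leak, slow drift and motion-coupled fluctuations are
  # all rank-structured; accumulate them through a single basis matmul
  # (the baseline intensity map rides along as an intercept column)
  tt <- seq_len(nt)
  basis <- cbind((l_wm + l_csf) / sqrt(2), scale(tt),
                 scale(cos(pi * (tt - 1) / (nt - 1))), fd, 1)
  coefs <- rbind(rep(noise$wm_csf_leak, nvox),
                 matrix(rnorm(2 * nvox,
                              sd = noise$drift_amplitude / sqrt(2)),
                        2, nvox),
                 runif(nvox, 0, noise$motion_coupling),
                 noise$baseline * runif(nvox, 0.95, 1.05))
  M <- M + basis %*% coefs

  # task-evoked responses in all labeled voxels
  roi_idx <- which(lab != 0L)
  if (length(ev) && nrow(ev) > 0 && any(task$amplitudes > 0)) {
    for (cn in unique(as.character(ev$trial_type))) {
      sel <- ev$trial_type == cn
      reg <- .task_regressor(ev$onset[sel], ev$duration[sel], tr, nt)
      amp <- if (cn %in% names(task$amplitudes)) task$amplitudes[[cn]] else 0.5
      if (amp > 0)
        M[, roi_idx] <- M[, roi_idx] +
          outer(reg, amp * runif(length(roi_idx), 0.5, 1.5))
    }
  }

  # global intensity spikes
  spike_volumes <- which(runif(nt) < noise$spike_rate)
  if (length(spike_volumes)) {
    dev <- noise$baseline * (noise$spike_magnitude / 100) *
      runif(length(spike_volumes), 1.2, 2)
    M[spike_volumes, ] <- M[spike_volumes, , drop = FALSE] + dev
  }

  structure(list(bold = .matrix_bold(M, dims), tr = tr, n_volumes = nt,
                 motion = motion, events = ev, subject_id = subject_id,
                 rng_seed = as.integer(seed), spike_volumes = spike_volumes,
                 latents = list(prc = l_prc, phc = l_phc, prc_private = l_prcp,
                                phc_private = l_phcp, wm = l_wm, csf = l_csf)),
            class = "subject_dataset")
}

#' Simulate a cohort sharing one atlas and ground truth
#'
#' Subjects share the common-space atlas and the planted gradient but
#' differ in latent signals, noise, motion and event timing through
#' per-subject derived seeds.
#'
#' @inheritParams simulate_subject
#' @param n_subjects Number of subjects (at least 2; group statistics are
#'   undefined below that).
#' @param seed Cohort-level seed from which per-subject seeds are derived.
#' @return An object of class `cohort`: list with `subjects` (list of
#'   `subject_dataset`), `atlas`, `truth`.
#' @export
simulate_cohort <- function(n_subjects, atlas, truth, noise = noise_spec(),
                            task = task_spec(), tr = 2, n_volumes = 370L,
                            seed = 1L) {
  if (n_subjects < 2L)
    stop("n_subjects must be at least 2", call. = FALSE)
  seeds <- .derive_seeds(seed, n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(i)
    simulate_subject(atlas, truth, noise, task, tr, n_volumes,
                     subject_id = sprintf("sub-%02d", i), seed = seeds[i]))
  structure(list(subjects = subjects, atlas = atlas, truth = truth,
                 seed = as.integer(seed)),
            class = "cohort")
}
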