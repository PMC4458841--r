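#' Restrict a Fisher-z map to a voxel subset
#'
#' @param map A `fisher_zmap`.
#' @param voxels Integer voxel indices (must all be covered by the map).
#' @return A `fisher_zmap` over exactly `voxels`.
#' @export
restrict_map <- function(map, voxels) {
  stopifnot(inherits(map, "fisher_zmap"))
  pos <- match(as.integer(voxels), map$voxels)
  if (anyNA(pos)) stop("map does not cover the requested voxels",
                       call. = FALSE)
  map$values <- map$values[pos]
  map$voxels <- map$voxels[pos]
  map$qc_zero_variance <- intersect(map$qc_zero_variance, map$voxels)
  map
}

#' Volume-level preprocessing of one simulated subject
#'
#' Spike flagging from the global intensity series and motion, spatial
#' smoothing, task GLM residualization, and extraction of the residual
#' time series over all labeled (non-background) voxels.
#'
#' @param dataset A `subject_dataset`.
#' @param atlas The `labeled_atlas` the subject was generated on.
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 1.5).
#' @return List with `residuals` (t x V_roi matrix), `roi_voxels`,
#'   `mean_intensity` (per ROI voxel, from the smoothed data),
#'   `spikes`, `design`, `motion`, `tr`, `subject_id`.
#' @export
preprocess_subject <- function(dataset, atlas, fwhm_mm = 1.5) {
  stopifnot(inherits(dataset, "subject_dataset"),
            inherits(atlas, "labeled_atlas"))
  roi_voxels <- which(atlas$labels != 0L)
  Y <- .bold_matrix(dataset$bold)
  spikes <- detect_spikes(rowMeans(Y), dataset$motion)
  sm <- gaussian_smooth(dataset$bold, fwhm_mm, atlas$voxel_size)
  Ys <- .bold_matrix(sm)[, roi_voxels, drop = FALSE]
  design <- build_task_design(dataset$events, dataset$motion, spikes,
                              dataset$tr, dataset$n_volumes)
  resid <- remove_task_effects(Ys, design)
  list(residuals = resid, roi_voxels = roi_voxels,
       mean_intensity = colMeans(Ys), spikes = spikes, design = design,
       motion = dataset$motion, tr = dataset$tr,
       subject_id = dataset$subject_id)
}

# Nuisance covariates: WM and CSF mean series, the six motion parameters
# and one indicator per flagged spike volume.
.nuisance_matrix <- function(prep, atlas) {
  col_of <- function(vox) match(vox, prep$roi_voxels)
  wm <- rowMeans(prep$residuals[, col_of(atlas_voxels(atlas, "WM")),
                                drop = FALSE])
  csf <- rowMeans(prep$residuals[, col_of(atlas_voxels(atlas, "CSF")),
                                 drop = FALSE])
  N <- cbind(wm = wm, csf = csf, prep$motion)
  if (nrow(prep$spikes) > 0) {
    for (v in sort(unique(prep$spikes$volume))) {
      ind <- numeric(nrow(N)); ind[v] <- 1
      N <- cbind(N, ind)
      colnames(N)[ncol(N)] <- sprintf("spike_%03d", v)
    }
  }
  N
}

# Seed conditioning: intensity thresholding then border erosion.
.condition_seed <- function(seed_vox, target_vox, prep, atlas,
                            gap_voxels = 2L) {
  cols <- match(seed_vox, prep$roi_voxels)
  # temporal-mean intensities act as a single-timepoint series here
  kept <- threshold_roi_intensity(seq_along(cols),
                                  matrix(prep$mean_intensity[cols],
                                         nrow = 1L))
  seed_vox <- seed_vox[kept]
  erode_seed_border(seed_vox, target_vox, gap_voxels,
                    dim = dim(atlas$labels))
}

#' First-level connectivity maps for one preprocessed subject
#'
#' Conditions each seed (intensity thresholding, border erosion against
#' the target), builds the nuisance set (WM/CSF series, motion, spike
#' indicators) and computes a standardized seed-to-voxel Fisher-z map
#' over the target voxels for every seed.
#'
#' @param prep Output of [preprocess_subject()].
#' @param atlas The `labeled_atlas`.
#' @param seeds Named list: seed id -> integer voxel indices (defaults to
#'   the PRC and PHC atlas regions).
#' @param target_voxels Integer indices of the mapping target (defaults
#'   to EC plus subiculum).
#' @param band Band-pass edges in Hz.
#' @param gap_voxels Seed-border erosion clearance.
#' @return Named list of standardized `fisher_zmap` objects.
#' @export
subject_zmaps <- function(prep, atlas, seeds = NULL, target_voxels = NULL,
                          band = c(0.01, 0.1), gap_voxels = 2L) {
  if (is.null(seeds))
    seeds <- list(PRC = atlas_voxels(atlas, "PRC"),
                  PHC = atlas_voxels(atlas, "PHC"))
  if (is.null(target_voxels))
    target_voxels <- sort(c(atlas_voxels(atlas, "EC"),
                            atlas_voxels(atlas, "SUB")))
  nuis <- .nuisance_matrix(prep, atlas)
  tcols <- match(target_voxels, prep$roi_voxels)
  if (anyNA(tcols)) stop("target voxels missing from the residual set",
                         call. = FALSE)
  out <- list()
  for (sid in names(seeds)) {
    sv <- .condition_seed(seeds[[sid]], target_voxels, prep, atlas,
                          gap_voxels)
    s_series <- rowMeans(prep$residuals[, match(sv, prep$roi_voxels),
                                        drop = FALSE])
    m <- seed_to_voxel_map(s_series, prep$residuals[, tcols, drop = FALSE],
                           target_voxels, nuis, band, prep$tr,
                           subject_id = prep$subject_id, seed_id = sid)
    out[[sid]] <- z_standardize(m)
  }
  out
}

#' Simulate and analyze a cohort through the first-level pipeline
#'
#' Streams subjects one at a time (simulate, preprocess, first-level
#' maps) so that full 4-D arrays never accumulate; keeps the compact
#' residual matrices over labeled voxels for later second-stage seeds
#' (e.g. EC-subregion seeds into the subiculum).
#'
#' @inheritParams simulate_cohort
#' @param fwhm_mm Smoothing FWHM (mm).
#' @param band Band-pass edges (Hz).
#' @param verbose Print per-subject progress?
#' @return List with `zmaps` (seed id -> list of `fisher_zmap` per
#'   subject), `preps` (per-subject compact preprocessing output),
#'   `subject_ids`, `atlas`, `truth`.
#' @export
run_first_level <- function(n_subjects, atlas, truth, noise = noise_spec(),
                            task = task_spec(), tr = 2, n_volumes = 370L,
                            seed = 1L, fwhm_mm = 1.5, band = c(0.01, 0.1),
                            verbose = FALSE) {
  if (n_subjects < 2L) stop("n_subjects must be at least 2", call. = FALSE)
  seeds <- .derive_seeds(seed, n_subjects)
  zmaps <- list(); preps <- list(); ids <- character(n_subjects)
  for (i in seq_len(n_subjects)) {
    ds <- simulate_subject(atlas, truth, noise, task, tr, n_volumes,
                           subject_id = sprintf("sub-%02d", i),
                           seed = seeds[i])
    prep <- preprocess_subject(ds, atlas, fwhm_mm)
    rm(ds)
    maps <- subject_zmaps(prep, atlas, band = band)
    ids[i] <- prep$subject_id
    for (sid in names(maps)) zmaps[[sid]][[i]] <- maps[[sid]]
    preps[[i]] <- prep
    if (verbose) message("subject ", i, "/", n_subjects, " done")
  }
  list(zmaps = zmaps, preps = preps, subject_ids = ids, atlas = atlas,
       truth = truth)
}

#' Second-stage connectivity maps for derived EC-subregion seeds
#'
#' Reuses the stored residuals to compute, per subject, standardized
#' seed-to-voxel maps from the anterior-lateral and posterior-medial EC
#' seed masks into the subiculum.
#'
#' @param fl Output of [run_first_level()].
#' @param seed_pair List with `al_ec` and `pm_ec` voxel index vectors
#'   (from [derive_subregion_seeds()] or [predicted_parcels()]).
#' @param band Band-pass edges (Hz).
#' @param gap_voxels Seed-border erosion clearance.
#' @return Named list (`alEC`, `pmEC`) of per-subject `fisher_zmap` over
#'   the subiculum.
#' @export
run_subregion_maps <- function(fl, seed_pair, band = c(0.01, 0.1),
                               gap_voxels = 2L) {
  sub_vox <- atlas_voxels(fl$atlas, "SUB")
  out <- list(alEC = list(), pmEC = list())
  seeds <- list(alEC = seed_pair$al_ec, pmEC = seed_pair$pm_ec)
  for (i in seq_along(fl$preps)) {
    maps <- subject_zmaps(fl$preps[[i]], fl$atlas, seeds = seeds,
                          target_voxels = sub_vox, band = band,
                          gap_voxels = gap_voxels)
    out$alEC[[i]] <- maps$alEC
    out$pmEC[[i]] <- maps$pmEC
  }
  out
}

#' Group-level EC gradient analysis
#'
#' Runs the voxelwise paired contrast over the EC with cluster-extent
#' permutation thresholding in both directions, the 2x2x2 within-subject
#' ANOVA on section means, and (optionally) the coordinate classifier
#' with its permutation null.
#'
#' @param fl Output of [run_first_level()].
#' @param n_perm Permutations for cluster inference.
#' @param z_thresh Cluster-forming threshold (default 2.3).
#' @param alpha Cluster-level alpha (default 0.05).
#' @param classifier Run the LOSO classifier?
#' @param n_iter Permutations for the classifier null.
#' @param seed RNG seed for both permutation schemes.
#' @return List with `paired` (`group_stat_map`), `clusters_prc`,
#'   `clusters_phc`, `cell_means`, `anova`, `sections`, and when
#'   requested `loso`, `perm`, `consistency`, `parcels`.
#' @export
run_gradient_analysis <- function(fl, n_perm = 1000L, z_thresh = 2.3,
                                  alpha = 0.05, classifier = TRUE,
                                  n_iter = 1000L, seed = 1L) {
  atlas <- fl$atlas
  ec_vox <- atlas_voxels(atlas, "EC")
  ec_prc <- lapply(fl$zmaps$PRC, restrict_map, voxels = ec_vox)
  ec_phc <- lapply(fl$zmaps$PHC, restrict_map, voxels = ec_vox)
  D <- stack_maps(ec_prc) - stack_maps(ec_phc)
  attr(D, "voxels") <- ec_vox
  paired <- one_sample_t(D, contrast_id = "PRC>PHC")
  negD <- -D; attr(negD, "voxels") <- ec_vox
  neg <- one_sample_t(negD, contrast_id = "PHC>PRC")
  dims <- dim(atlas$labels)
  sds <- .derive_seeds(seed, 3L)
  clusters_prc <- cluster_threshold(paired, D, dims, z_thresh, alpha,
                                    n_perm, seed = sds[1])
  clusters_phc <- cluster_threshold(neg, negD, dims, z_thresh, alpha,
                                    n_perm, seed = sds[2])

  sections <- section_assignment(atlas, "EC")
  cm <- do.call(rbind, c(
    lapply(ec_prc, section_means, sections = sections),
    lapply(ec_phc, section_means, sections = sections)))
  anova <- rm_anova_2x2x2(cm)

  out <- list(paired = paired, paired_neg = neg,
              clusters_prc = clusters_prc, clusters_phc = clusters_phc,
              cell_means = cm, anova = anova, sections = sections)
  if (classifier) {
    prefs <- Map(subject_preference_map, ec_prc, ec_phc)
    ds <- assemble_samples(prefs, dims)
    out$loso <- loso_svm(ds)
    out$perm <- permutation_null(ds, out$loso, n_iter = n_iter,
                                 seed = sds[3])
    out$consistency <- consistency_map(out$loso, ds)
    out$parcels <- predicted_parcels(out$loso, ds$voxels)
    out$samples <- ds
  }
  out
}

#' Group-level subiculum gradient analysis
#'
#' For a pair of seed-map lists over the subiculum (EC subregions or
#' PRC/PHC), computes the section cell means, the 2x2x2 within-subject
#' ANOVA (seed x longitudinal x proximo-distal) and the end-slice paired
#' contrasts.
#'
#' @param maps_a,maps_b Per-subject `fisher_zmap` lists over the
#'   subiculum for the two seeds.
#' @param atlas The `labeled_atlas`.
#' @param k End-slice count for the end contrasts (default 8).
#' @return List with `cell_means`, `anova`, `end_anterior`,
#'   `end_posterior`, `sections`.
#' @export
run_subiculum_analysis <- function(maps_a, maps_b, atlas, k = 8L) {
  sections <- section_assignment(atlas, "SUB",
                                 quintiles = FALSE)
  cm <- do.call(rbind, c(
    lapply(maps_a, section_means, sections = sections),
    lapply(maps_b, section_means, sections = sections)))
  list(cell_means = cm, anova = rm_anova_2x2x2(cm),
       end_anterior = end_slices_contrast(maps_a, maps_b, sections, k,
                                          "anterior"),
       end_posterior = end_slices_contrast(maps_a, maps_b, sections, k,
                                           "posterior"),
       sections = sections)
}
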