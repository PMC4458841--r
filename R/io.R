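#' Write a subject dataset to disk
#'
#' BOLD as 4-D NIfTI-1, motion as 6-column TSV, events as TSV with
#' columns `onset`, `duration`, `trial_type`.
#'
#' @param dataset A `subject_dataset`.
#' @param dir Output directory (created if needed).
#' @param voxel_mm Voxel size written to the NIfTI header.
#' @return Invisibly, the paths written.
#' @export
write_subject <- function(dataset, dir, voxel_mm = 0.8) {
  stopifnot(inherits(dataset, "subject_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(bold = file.path(dir, "bold.nii.gz"),
             motion = file.path(dir, "motion.tsv"),
             events = file.path(dir, "events.tsv"))
  img <- RNifti::asNifti(dataset$bold)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, paths["bold"])
  write.table(dataset$motion, paths["motion"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(dataset$events, paths["events"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a 4-D BOLD NIfTI volume
#' @param path NIfTI file path.
#' @return Plain numeric array.
#' @export
read_bold <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim(arr))
}

#' Read a motion-parameter TSV (t x 6)
#' @param path TSV path with a header row.
#' @return Numeric matrix.
#' @export
read_motion <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t"))
}

#' Read an events TSV (onset, duration, trial_type)
#' @param path TSV path with a header row.
#' @return Data frame.
#' @export
read_events <- function(path) {
  ev <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("events file needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ev
}

#' Write an atlas (and optional ground-truth weights) to disk
#'
#' The label grid is written as integer NIfTI; when a `ground_truth` is
#' supplied its EC mixing weights are written as a 3-D float NIfTI with
#' `NA` outside the EC.
#'
#' @param atlas A `labeled_atlas`.
#' @param dir Output directory.
#' @param truth Optional `ground_truth`.
#' @return Invisibly, the paths written.
#' @export
write_atlas <- function(atlas, dir, truth = NULL) {
  stopifnot(inherits(atlas, "labeled_atlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(labels = file.path(dir, "atlas.nii.gz"))
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- rep(atlas$voxel_size, 3)
  RNifti::writeNifti(img, paths["labels"])
  if (!is.null(truth)) {
    w <- array(NA_real_, dim(atlas$labels))
    w[truth$ec$voxel] <- truth$ec$weight
    paths <- c(paths, weights = file.path(dir, "ec_weights.nii.gz"))
    wi <- RNifti::asNifti(w)
    RNifti::pixdim(wi) <- rep(atlas$voxel_size, 3)
    RNifti::writeNifti(wi, paths["weights"])
  }
  invisible(paths)
}

#' Write a cohort to disk with a JSON manifest
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory; one subdirectory per subject.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, dir, cohort$truth)
  entries <- lapply(cohort$subjects, function(s) {
    sd <- file.path(dir, s$subject_id)
    write_subject(s, sd, voxel_mm = cohort$atlas$voxel_size)
    list(subject_id = s$subject_id, dir = s$subject_id,
         n_volumes = s$n_volumes, tr = s$tr, rng_seed = s$rng_seed)
  })
  manifest <- list(n_subjects = length(cohort$subjects),
                   seed = cohort$seed,
                   grid_shape = dim(cohort$atlas$labels),
                   voxel_size = cohort$atlas$voxel_size,
                   subjects = entries)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mp)
}

#' Write a Fisher-z map as NIfTI plus JSON sidecar
#'
#' Values outside the target mask are `NA`; the sidecar records subject,
#' seed, band and effective df.
#'
#' @param map A `fisher_zmap`.
#' @param dim Grid shape.
#' @param path Output NIfTI path (`.nii.gz`); the sidecar replaces the
#'   extension with `.json`.
#' @param voxel_mm Voxel size for the header.
#' @return Invisibly, the two paths.
#' @export
write_zmap <- function(map, dim, path, voxel_mm = 0.8) {
  stopifnot(inherits(map, "fisher_zmap"))
  arr <- array(NA_real_, dim)
  arr[map$voxels] <- map$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(subject_id = map$subject_id,
                            seed_id = map$seed_id, band = map$band,
                            df_effective = map$df_effective,
                            n_zero_variance = length(map$qc_zero_variance)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' Write a cluster table as TSV
#'
#' Columns `cluster_id`, `size`, `peak_z`, `x`, `y`, `z`, `p_fwe`.
#'
#' @param clusters A `cluster_table`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_cluster_table <- function(clusters, path) {
  write.table(as.data.frame(clusters), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
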