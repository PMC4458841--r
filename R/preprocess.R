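#' Flag spike volumes from global intensity and scan-to-scan motion
#'
#' A volume is flagged `"intensity"` when its global mean deviates from
#' the run mean by more than `intensity_pct` percent, and `"motion"` when
#' the scan-to-scan displacement exceeds `motion_mm`.  Displacement is the
#' Euclidean norm of the volume-to-volume difference of the six motion
#' parameters after converting rotations to mm at a 65 mm head radius
#' (the common ART convention).
#'
#' @param bold_global_mean Numeric series of global mean intensities.
#' @param motion t x 6 matrix (3 translations in mm, 3 rotations in rad).
#' @param intensity_pct Percent-deviation threshold (default 1.3).
#' @param motion_mm Scan-to-scan displacement threshold in mm (default 0.3).
#' @param head_radius_mm Radius for the rotation-to-mm conversion.
#' @return An object of class `spike_set`: data frame with columns
#'   `volume` (1-based index) and `reason`; attribute `n_volumes`.
#' @export
detect_spikes <- function(bold_global_mean, motion, intensity_pct = 1.3,
                          motion_mm = 0.3, head_radius_mm = 65) {
  g <- as.numeric(bold_global_mean)
  nt <- length(g)
  motion <- as.matrix(motion)
  if (nt < 2L || nrow(motion) != nt)
    stop("global series and motion must have equal length >= 2",
         call. = FALSE)
  mg <- mean(g)
  if (mg == 0) stop("global mean intensity is zero: percent deviation ",
                    "undefined", call. = FALSE)
  int_flag <- which(abs(g - mg) / abs(mg) * 100 > intensity_pct)

  mm <- motion
  mm[, 4:6] <- mm[, 4:6] * head_radius_mm
  disp <- sqrt(rowSums(diff(mm)^2))
  mot_flag <- which(disp > motion_mm) + 1L

  df <- rbind(
    if (length(int_flag)) data.frame(volume = int_flag, reason = "intensity"),
    if (length(mot_flag)) data.frame(volume = mot_flag, reason = "motion"))
  if (is.null(df)) df <- data.frame(volume = integer(0),
                                    reason = character(0))
  df <- df[!duplicated(df$volume), , drop = FALSE]
  df <- df[order(df$volume), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_volumes = nt, class = c("spike_set", "data.frame"))
}

# Truncated, renormalized 1-D Gaussian kernel as a band matrix operator.
.gauss_op <- function(n, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    kk <- k[j - i + r + 1L]
    A[i, j] <- kk / sum(kk)
  }
  A
}

#' Spatial Gaussian smoothing of a 4-D BOLD array
#'
#' Separable per-volume Gaussian convolution with
#' `sigma = fwhm_mm / (2 sqrt(2 ln 2)) / voxel_mm` voxels.  Kernels are
#' truncated at 4 sigma and renormalized at the array boundary.
#' `fwhm_mm = 0` returns the input unchanged.
#'
#' @param bold 4-D (x,y,z,t) array, or 3-D volume.
#' @param fwhm_mm Full width at half maximum in mm (default 1.5).
#' @param voxel_mm Isotropic voxel size in mm.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(bold, fwhm_mm = 1.5, voxel_mm) {
  if (fwhm_mm < 0) stop("fwhm_mm must be nonnegative", call. = FALSE)
  if (fwhm_mm == 0) return(bold)
  .assert_scalar_number(voxel_mm, "voxel_mm")
  d <- dim(bold)
  three_d <- length(d) == 3L
  if (three_d) { bold <- array(bold, c(d, 1L)); d <- dim(bold) }
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  out <- bold
  for (ax in 1:3) {
    A <- .gauss_op(d[ax], sigma)
    perm <- c(ax, setdiff(1:4, ax))
    m <- matrix(aperm(out, perm), nrow = d[ax])
    m <- A %*% m
    out <- aperm(array(m, dim = d[perm]), order(perm))
  }
  if (three_d) out <- array(out, d[1:3])
  out
}

#' Build the task GLM design matrix
#'
#' One HRF-convolved boxcar column per task condition (sampled at volume
#' times), six motion columns, one 0/1 indicator column per flagged spike
#' volume (duplicates collapsed), and an intercept.
#'
#' @param events Data frame with `onset`, `duration`, `trial_type` (or a
#'   [task_spec()] carrying explicit events).
#' @param motion t x 6 motion parameter matrix.
#' @param spikes A `spike_set` (or `NULL` for none).
#' @param tr Repetition time (s).
#' @param n_volumes Number of volumes.
#' @return An object of class `design_matrix`: numeric matrix with named
#'   columns, intercept last.
#' @export
build_task_design <- function(events, motion, spikes = NULL, tr, n_volumes) {
  if (inherits(events, "task_spec")) events <- events$events
  n_volumes <- as.integer(n_volumes)
  cols <- list()
  if (!is.null(events) && nrow(events) > 0) {
    if (any(events$onset < 0) ||
        any(events$onset >= tr * n_volumes))
      stop("event onsets must lie within the run", call. = FALSE)
    for (cn in unique(as.character(events$trial_type))) {
      sel <- events$trial_type == cn
      cols[[paste0("task_", cn)]] <-
        .task_regressor(events$onset[sel], events$duration[sel], tr,
                        n_volumes)
    }
  }
  motion <- as.matrix(motion)
  if (nrow(motion) != n_volumes)
    stop("motion must have n_volumes rows", call. = FALSE)
  mn <- colnames(motion)
  if (is.null(mn)) mn <- paste0("motion_", 1:6)
  for (j in 1:6) cols[[mn[j]]] <- motion[, j]
  if (!is.null(spikes) && nrow(spikes) > 0) {
    vols <- sort(unique(spikes$volume))
    if (any(vols < 1L) || any(vols > n_volumes))
      stop("flagged volume index out of range", call. = FALSE)
    for (v in vols) {
      ind <- numeric(n_volumes); ind[v] <- 1
      cols[[sprintf("spike_%03d", v)]] <- ind
    }
  }
  cols[["intercept"]] <- rep(1, n_volumes)
  X <- do.call(cbind, cols)
  X <- X[, !duplicated(t(X)), drop = FALSE]
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient after dropping duplicates",
         call. = FALSE)
  structure(X, class = c("design_matrix", class(X)))
}

#' Remove task effects by voxelwise OLS
#'
#' Fits the design to every voxel's time series by ordinary least squares
#' and returns the residual images; residuals are orthogonal to every
#' design column.
#'
#' @param bold 4-D (x,y,z,t) array or t x V matrix.
#' @param design Design matrix with `n_volumes` rows (see
#'   [build_task_design()]); it must contain any intercept wanted.
#' @return Residuals with the same shape as `bold`.
#' @export
remove_task_effects <- function(bold, design) {
  X <- unclass(design)
  is4d <- length(dim(bold)) == 4L
  Y <- if (is4d) .bold_matrix(bold) else as.matrix(bold)
  if (nrow(Y) != nrow(X))
    stop("design rows must equal the number of volumes", call. = FALSE)
  keep <- !duplicated(t(X))
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  R <- Y - X %*% qr.coef(qrX, Y)
  if (is4d) .matrix_bold(R, dim(bold)[1:3]) else R
}

#' Drop low-intensity (dropout-prone) voxels from an ROI
#'
#' Removes voxels whose temporal-mean intensity lies more than two SDs
#' below the across-voxel mean intensity of the ROI.
#'
#' @param mask Logical array or integer voxel indices.
#' @param bold 4-D array or t x V matrix over the full grid.
#' @param n_sd Number of SDs below the mean that defines removal.
#' @return Mask of the same type as the input (possibly smaller).
#' @export
threshold_roi_intensity <- function(mask, bold, n_sd = 2) {
  logical_in <- is.logical(mask)
  idx <- if (logical_in) which(mask) else as.integer(mask)
  if (!length(idx)) stop("mask is empty", call. = FALSE)
  if (length(idx) == 1L) return(mask)
  Y <- if (length(dim(bold)) == 4L) .bold_matrix(bold) else as.matrix(bold)
  mv <- colMeans(Y[, idx, drop = FALSE])
  keep <- mv >= mean(mv) - n_sd * sd(mv)
  if (!any(keep))
    stop("intensity thresholding removed every voxel in the ROI",
         call. = FALSE)
  idx <- idx[keep]
  if (logical_in) {
    out <- mask & FALSE
    out[idx] <- TRUE
    out
  } else idx
}

#' Erode a seed mask away from a target mask
#'
#' Removes seed voxels lying within Chebyshev (chessboard) distance
#' `gap_voxels` of any target voxel, leaving a clear gap so seed and
#' target series share no adjacent voxels (autocorrelation control).
#'
#' @param seed_mask,target_mask Logical arrays of identical shape, or
#'   integer voxel index vectors (then `dim` is required).
#' @param gap_voxels Required clearance in voxels (default 2).
#' @param dim Grid shape when masks are given as indices.
#' @return Eroded seed mask, same type as the input.
#' @export
erode_seed_border <- function(seed_mask, target_mask, gap_voxels = 2L,
                              dim = NULL) {
  logical_in <- is.logical(seed_mask)
  if (logical_in) {
    dim <- base::dim(seed_mask)
    seed_idx <- which(seed_mask); targ_idx <- which(target_mask)
  } else {
    if (is.null(dim)) stop("dim required for index masks", call. = FALSE)
    seed_idx <- as.integer(seed_mask); targ_idx <- as.integer(target_mask)
  }
  if (length(intersect(seed_idx, targ_idx)))
    stop("seed and target masks must be disjoint", call. = FALSE)
  if (gap_voxels <= 0 || !length(targ_idx) || !length(seed_idx)) {
    keep <- rep(TRUE, length(seed_idx))
  } else {
    sc <- .vox_coords(seed_idx, dim); tc <- .vox_coords(targ_idx, dim)
    keep <- vapply(seq_along(seed_idx), function(i) {
      d <- pmax(abs(tc[, 1] - sc[i, 1]), abs(tc[, 2] - sc[i, 2]),
                abs(tc[, 3] - sc[i, 3]))
      min(d) > gap_voxels
    }, logical(1))
  }
  if (!any(keep))
    stop("seed-border erosion removed the entire seed", call. = FALSE)
  out_idx <- seed_idx[keep]
  if (logical_in) {
    out <- seed_mask & FALSE
    out[out_idx] <- TRUE
    out
  } else out_idx
}
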