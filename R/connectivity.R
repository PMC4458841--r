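#' Mean time series over a mask
#'
#' @param bold 4-D (x,y,z,t) array or t x V matrix over the full grid.
#' @param mask Logical array or integer voxel indices.
#' @return Numeric series of length t (unweighted mean across voxels).
#' @export
mean_timeseries <- function(bold, mask) {
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (!length(idx)) stop("mask is empty", call. = FALSE)
  Y <- if (length(dim(bold)) == 4L) .bold_matrix(bold) else as.matrix(bold)
  rowMeans(Y[, idx, drop = FALSE])
}

#' Regress nuisance covariates out of time series
#'
#' OLS residual against the nuisance set plus an intercept; with an empty
#' nuisance set this mean-centers the input.  Output columns are
#' orthogonal to every nuisance column.
#'
#' @param x Numeric series or t x V matrix.
#' @param nuisance t x q matrix (may have zero columns or be `NULL`).
#' @return Residuals, same shape as `x`.
#' @export
regress_nuisance <- function(x, nuisance = NULL) {
  one_col <- is.null(dim(x))
  Y <- if (one_col) matrix(x, ncol = 1L) else as.matrix(x)
  if (is.null(nuisance) || NCOL(nuisance) == 0L ||
      (is.matrix(nuisance) && ncol(nuisance) == 0L)) {
    X <- matrix(1, nrow(Y), 1L)
  } else {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nrow(Y))
      stop("nuisance rows must match the series length", call. = FALSE)
    if (ncol(nuisance) >= nrow(Y))
      stop("more nuisance regressors than time points", call. = FALSE)
    X <- cbind(intercept = 1, nuisance)
    X <- X[, !duplicated(t(X)), drop = FALSE]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("nuisance set is rank deficient", call. = FALSE)
  R <- Y - X %*% qr.coef(qrX, Y)
  if (one_col) R[, 1L] else R
}

#' Fisher z-transform of correlation coefficients
#'
#' `z = atanh(r)`, with `|r|` clipped to `1 - 1e-7` first so degenerate
#' correlations stay finite.
#'
#' @param r Numeric correlations in `[-1, 1]`.
#' @return Fisher-z values.
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r)) stop("r must be numeric", call. = FALSE)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  atanh(r)
}

#' Seed-to-voxel Fisher-z connectivity map
#'
#' Per target voxel: nuisance regression of both the seed and the voxel
#' series, zero-phase band-pass filtering of both, Pearson correlation,
#' and Fisher z-transform.  Voxels with zero variance after filtering get
#' `z = 0` and are recorded in the QC list.
#'
#' @param seed_series Seed mean time series (length t).
#' @param data t x V matrix of target voxel series (columns follow
#'   `voxels`).
#' @param voxels Integer voxel indices identifying the columns of `data`.
#' @param nuisance t x q nuisance matrix (or `NULL`).
#' @param band Band edges in Hz (default `c(0.01, 0.1)`).
#' @param tr Repetition time (s).
#' @param subject_id,seed_id Identifiers stored with the map.
#' @return An object of class `fisher_zmap`: `values` (z per voxel),
#'   `voxels`, `subject_id`, `seed_id`, `band`, `df_effective`,
#'   `qc_zero_variance`.
#' @export
seed_to_voxel_map <- function(seed_series, data, voxels, nuisance = NULL,
                              band = c(0.01, 0.1), tr,
                              subject_id = "sub", seed_id = "seed") {
  data <- as.matrix(data)
  if (length(seed_series) != nrow(data))
    stop("seed series and data must share the time dimension", call. = FALSE)
  if (length(voxels) != ncol(data))
    stop("one voxel index per data column required", call. = FALSE)
  all_ts <- cbind(seed_series, data)
  all_ts <- regress_nuisance(all_ts, nuisance)
  all_ts <- bandpass(all_ts, band[1], band[2], tr)
  s <- all_ts[, 1L]
  V <- all_ts[, -1L, drop = FALSE]
  sdv <- apply(V, 2L, sd)
  sds <- sd(s)
  ok <- sdv > 1e-12 & sds > 1e-12
  r <- numeric(ncol(V))
  if (any(ok)) {
    sc <- (s - mean(s)) / sds
    Vc <- sweep(V[, ok, drop = FALSE], 2, colMeans(V[, ok, drop = FALSE]))
    r[ok] <- as.vector(crossprod(Vc, sc)) /
      ((nrow(V) - 1) * sdv[ok])
  }
  z <- fisher_z(r)
  z[!ok] <- 0
  # crude effective df: time points scaled by the analyzed bandwidth
  dfe <- max(2L, round(length(s) * 2 * (band[2] - band[1]) * tr) -
               NCOL(nuisance) - 1L)
  structure(list(values = z, voxels = as.integer(voxels),
                 subject_id = subject_id, seed_id = seed_id, band = band,
                 df_effective = dfe,
                 qc_zero_variance = as.integer(voxels)[!ok]),
            class = "fisher_zmap")
}

#' Z-standardize a Fisher-z map
#'
#' Subtracts the mean and divides by the SD of the map values within a
#' reference set of voxels (by default, every voxel the map covers).
#'
#' @param map A `fisher_zmap`.
#' @param reference_mask Optional integer voxel indices (a subset of
#'   `map$voxels`, at least 2) defining the standardization domain.
#' @return The standardized `fisher_zmap`.
#' @export
z_standardize <- function(map, reference_mask = NULL) {
  stopifnot(inherits(map, "fisher_zmap"))
  if (is.null(reference_mask)) {
    ref <- rep(TRUE, length(map$values))
  } else {
    ref <- map$voxels %in% as.integer(reference_mask)
  }
  if (sum(ref) < 2L)
    stop("reference mask must cover at least 2 map voxels", call. = FALSE)
  m <- mean(map$values[ref]); s <- sd(map$values[ref])
  if (s == 0) stop("zero SD over the reference mask", call. = FALSE)
  map$values <- (map$values - m) / s
  map
}
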