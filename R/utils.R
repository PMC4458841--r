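#' @useDynLib ectopo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor qnorm pt pf var aggregate quantile
#' @importFrom utils head tail write.table read.table
NULL

# Linear voxel indices <-> integer coordinates for a 3-D grid.
.vox_coords <- function(voxels, dim) {
  arrayInd(voxels, .dim = dim)
}

.coords_vox <- function(coords, dim) {
  as.integer(coords[, 1] + dim[1] * (coords[, 2] - 1) +
               dim[1] * dim[2] * (coords[, 3] - 1))
}

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# Flatten a 4-D (x,y,z,t) array into a t x V matrix (time in rows).
.bold_matrix <- function(bold) {
  d <- dim(bold)
  if (length(d) != 4L) stop("expected a 4-D (x,y,z,t) array", call. = FALSE)
  t(matrix(bold, nrow = prod(d[1:3]), ncol = d[4]))
}

# Inverse of .bold_matrix
.matrix_bold <- function(mat, spatial_dim) {
  array(t(mat), dim = c(spatial_dim, nrow(mat)))
}

# Residuals of columns of y against design X (with QR reuse);
# X must include any intercept the caller wants.
.ols_residuals <- function(y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design is rank deficient", call. = FALSE)
  y - X %*% qr.coef(qrX, y)
}

# Deterministic per-stream child seeds below 2^31.
.derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
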