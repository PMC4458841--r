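# Zero-phase IIR filtering for multi-column time series.
#
# The band-pass used throughout is a second-order Butterworth applied
# forward and backward (so the effective magnitude response is squared and
# the phase is zero).  Filtering is implemented directly on t x V matrices
# in direct-form-II-transposed, which keeps per-voxel work vectorized.

# Normalize (b, a) to equal length with a[1] = 1.
.iir_norm <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  m <- max(length(a), length(b)) - 1L
  list(b = c(b, rep(0, m + 1L - length(b))),
       a = c(a, rep(0, m + 1L - length(a))), m = m)
}

# Steady-state direct-form-II-transposed state for a unit-step input
# (the classic lfilter_zi construction): scaling this by the first
# sample gives initial conditions that start the filter in steady state,
# so step inputs produce no start-up transient.
.iir_zi <- function(b, a) {
  nm <- .iir_norm(b, a); b <- nm$b; a <- nm$a; m <- nm$m
  comp <- matrix(0, m, m)
  comp[1, ] <- -a[-1]
  if (m > 1L) comp[cbind(2:m, 1:(m - 1L))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(m) - t(comp), B)
}

# One forward pass of an IIR filter down the rows of X (time in rows),
# with per-column initial state zi_scale applied as zi %o% X[1, ].
.iir_filter_mat <- function(b, a, X, zi = NULL) {
  nm <- .iir_norm(b, a); b <- nm$b; a <- nm$a; m <- nm$m
  nt <- nrow(X); nv <- ncol(X)
  Y <- matrix(0, nt, nv)
  z <- if (is.null(zi)) matrix(0, m, nv) else zi %o% X[1L, ]
  for (t in seq_len(nt)) {
    x <- X[t, ]
    y <- b[1] * x + z[1, ]
    if (m > 1L) {
      for (i in seq_len(m - 1L)) {
        z[i, ] <- b[i + 1L] * x + z[i + 1L, ] - a[i + 1L] * y
      }
    }
    z[m, ] <- b[m + 1L] * x - a[m + 1L] * y
    Y[t, ] <- y
  }
  Y
}

# Zero-phase filtering: odd-reflection padding at both ends plus
# steady-state initial conditions on each pass.
.filtfilt_mat <- function(b, a, X) {
  one_col <- is.null(dim(X))
  if (one_col) X <- matrix(X, ncol = 1L)
  nt <- nrow(X)
  ext <- min(nt - 1L, max(3L * (max(length(a), length(b)) - 1L), 24L))
  if (ext < 1L) stop("series too short to filter", call. = FALSE)
  zi <- .iir_zi(b, a)
  front <- 2 * matrix(X[1L, ], ext, ncol(X), byrow = TRUE) -
    X[(ext + 1L):2L, , drop = FALSE]
  back <- 2 * matrix(X[nt, ], ext, ncol(X), byrow = TRUE) -
    X[(nt - 1L):(nt - ext), , drop = FALSE]
  Xp <- rbind(front, X, back)
  Y <- .iir_filter_mat(b, a, Xp, zi)
  Y <- .iir_filter_mat(b, a, Y[nrow(Y):1L, , drop = FALSE], zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y <- Y[(ext + 1L):(ext + nt), , drop = FALSE]
  if (one_col) Y[, 1L] else Y
}

#' Band-pass filter BOLD time series
#'
#' Zero-phase second-order Butterworth band-pass, applied forward and
#' backward.  The DC component is removed exactly (the filter has zeros at
#' zero frequency), pass-band amplitudes are preserved to within a few
#' percent, and frequencies well outside the band are strongly attenuated.
#'
#' @param x Numeric vector (one series) or t x V matrix (time in rows).
#' @param low,high Band edges in Hz. Defaults 0.01 and 0.1, the
#'   conventional low-frequency window for intrinsic connectivity.
#' @param tr Repetition time in seconds (sampling interval).
#' @return Filtered object of the same shape as `x`.
#' @export
bandpass <- function(x, low = 0.01, high = 0.1, tr) {
  .assert_scalar_number(tr, "tr")
  nyq <- 1 / (2 * tr)
  if (low < 0 || low >= high) stop("need 0 <= low < high", call. = FALSE)
  if (high >= nyq)
    stop(sprintf("high edge %.4g Hz is at or above Nyquist (%.4g Hz)",
                 high, nyq), call. = FALSE)
  # a zero low edge degenerates the band-pass design (pole at DC);
  # use the corresponding low-pass instead, which keeps DC
  bf <- if (low == 0) signal::butter(2, high / nyq, type = "low")
  else signal::butter(2, c(low, high) / nyq, type = "pass")
  .filtfilt_mat(bf$b, bf$a, x)
}

# Low-pass companion used by the synthetic-signal generator.
.lowpass <- function(x, cutoff, tr) {
  nyq <- 1 / (2 * tr)
  bf <- signal::butter(2, cutoff / nyq, type = "low")
  .filtfilt_mat(bf$b, bf$a, x)
}
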