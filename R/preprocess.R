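#' Discard initial volumes
#'
#' Removes the first `n_drop` time points of a series (magnetisation
#' equilibration volumes); remaining values are untouched.
#'
#' @param series A [bold_series()].
#' @param n_drop Non-negative integer, strictly less than T.
#' @return A [bold_series()] with `T - n_drop` time points.
#' @export
drop_initial_volumes <- function(series, n_drop = 10L) {
  n_drop <- as.integer(n_drop)
  if (n_drop < 0L) stop("'n_drop' must be >= 0")
  if (n_drop >= series$n_timepoints)
    stop("'n_drop' (", n_drop, ") must be < number of time points (",
         series$n_timepoints, ")")
  if (n_drop == 0L) return(series)
  series_with_data(series, series$data[-seq_len(n_drop), , drop = FALSE])
}

#' Remove per-voxel linear trends
#'
#' Subtracts from every voxel's series its ordinary-least-squares fit on
#' `(1, t)`, removing systematic scanner drift. Residuals have zero mean and
#' zero covariance with time.
#'
#' @param series A [bold_series()] with T >= 3.
#' @return Detrended [bold_series()].
#' @export
detrend_linear <- function(series) {
  nt <- series$n_timepoints
  if (nt < 3L) stop("need at least 3 time points to detrend")
  X <- cbind(1, seq_len(nt))
  series_with_data(series, stats::lsfit(X, series$data,
                                        intercept = FALSE)$residuals)
}

#' Ideal band-pass filter
#'
#' Frequency-domain rectangular filter: discrete-Fourier bins whose
#' frequency falls in `[low_hz, high_hz]` are retained, all others
#' (including DC, always) are zeroed; the filtered series is the real part
#' of the inverse transform. This is the conventional resting-state band of
#' 0.01-0.08 Hz by default.
#'
#' @param series A [bold_series()].
#' @param low_hz,high_hz Pass-band edges in Hz; `0 < low_hz < high_hz` and
#'   `high_hz` below the Nyquist frequency `1 / (2 * tr_seconds)`.
#' @return Filtered [bold_series()].
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.08) {
  nyquist <- 1 / (2 * series$tr_seconds)
  if (low_hz < 0 || high_hz <= low_hz || high_hz >= nyquist)
    stop("band must satisfy 0 <= low < high < Nyquist (",
         format(nyquist), " Hz)")
  nt <- series$n_timepoints
  k <- 0:(nt - 1)
  freq <- pmin(k, nt - k) / (nt * series$tr_seconds)
  keep <- freq >= low_hz & freq <= high_hz & k != 0L
  ft <- stats::mvfft(series$data)
  ft[!keep, ] <- 0
  out <- Re(stats::mvfft(ft, inverse = TRUE)) / nt
  series_with_data(series, out)
}

#' Nuisance regressor design
#'
#' Assembles the standard confound design: intercept, the six rigid-body
#' motion parameters, mean white-matter signal, mean CSF signal and (by
#' default) the global mean signal. Tissue means are computed from a series
#' covering the whole brain mask; compartment masks come from the phantom
#' (or any segmentation on the same grid).
#'
#' @param series A [bold_series()] over the full brain mask.
#' @param motion T x 6 motion parameter matrix (may be NULL to omit).
#' @param wm_mask,csf_mask Optional [brain_mask()]s on the same grid.
#' @param global_signal Include the mean over the series' own mask
#'   (default TRUE).
#' @return T x k numeric matrix with named columns, first column `intercept`.
#' @export
nuisance_design <- function(series, motion = NULL, wm_mask = NULL,
                            csf_mask = NULL, global_signal = TRUE) {
  nt <- series$n_timepoints
  X <- matrix(1, nt, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(motion)) {
    if (nrow(motion) != nt)
      stop("motion has ", nrow(motion), " rows but series has ", nt,
           " time points")
    if (ncol(motion) != 6L) stop("motion must have 6 columns")
    colnames(motion) <- paste0("motion_", 1:6)
    X <- cbind(X, motion)
  }
  tissue_mean <- function(tmask, label) {
    stopifnot_same_grid(series$grid, tmask$grid)
    cols <- match(tmask$indices, series$mask$indices)
    cols <- cols[!is.na(cols)]
    if (!length(cols)) stop("no ", label, " voxels inside the series mask")
    rowMeans(series$data[, cols, drop = FALSE])
  }
  if (!is.null(wm_mask))
    X <- cbind(X, wm = tissue_mean(wm_mask, "white-matter"))
  if (!is.null(csf_mask))
    X <- cbind(X, csf = tissue_mean(csf_mask, "CSF"))
  if (global_signal)
    X <- cbind(X, global = rowMeans(series$data))
  X
}

#' Regress nuisance signals out of every voxel
#'
#' Replaces each voxel's series with the residual of its least-squares
#' projection onto the design; residuals are orthogonal to every design
#' column. The design must be full column rank.
#'
#' @param series A [bold_series()].
#' @param design T x k numeric matrix (see [nuisance_design()]).
#' @return Residual [bold_series()].
#' @export
regress_nuisance <- function(series, design) {
  design <- as.matrix(design)
  if (nrow(design) != series$n_timepoints)
    stop("design has ", nrow(design), " rows but series has ",
         series$n_timepoints, " time points")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    dropped <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  series_with_data(series, qr.resid(qrX, series$data))
}

#' Power framewise displacement
#'
#' Per-volume head-motion summary: the sum of absolute backward differences
#' of the three translations plus the rotation differences converted to arc
#' length on a sphere of radius `sphere_radius_mm` (50 mm by convention).
#' The first volume's FD is 0.
#'
#' @param motion T x 6 matrix: translations (mm) then rotations (radians).
#' @param sphere_radius_mm Rotation-to-displacement conversion radius.
#' @return List with `fd` (length-T vector, mm) and `mean_fd`.
#' @export
power_fd <- function(motion, sphere_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion must have 6 columns (3 translations, 3 rotations)")
  if (nrow(motion) < 2L) stop("need at least 2 volumes")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd))
}

#' Full temporal preprocessing pipeline
#'
#' Fixed order: drop initial volumes, linear detrend, band-pass filter,
#' nuisance regression. Motion regressors are truncated to match the
#' dropped volumes.
#'
#' @param series A [bold_series()].
#' @param motion T x 6 motion matrix aligned with the raw series.
#' @param n_drop Initial volumes to discard (default 10).
#' @param low_hz,high_hz Pass band (defaults 0.01, 0.08).
#' @param wm_mask,csf_mask,global_signal Passed to [nuisance_design()];
#'   tissue means are computed after filtering, from the same cleaned data
#'   the voxels are regressed against.
#' @return List with `series` (cleaned [bold_series()]), `mean_fd`, and
#'   `design` (the nuisance design used).
#' @export
preprocess_bold <- function(series, motion = NULL, n_drop = 10L,
                            low_hz = 0.01, high_hz = 0.08,
                            wm_mask = NULL, csf_mask = NULL,
                            global_signal = TRUE) {
  fd <- if (!is.null(motion)) power_fd(motion)$mean_fd else NA_real_
  s <- drop_initial_volumes(series, n_drop)
  if (!is.null(motion)) {
    if (nrow(motion) != series$n_timepoints)
      stop("motion rows must match the raw series length")
    if (n_drop > 0L) motion <- motion[-seq_len(n_drop), , drop = FALSE]
  }
  s <- detrend_linear(s)
  s <- bandpass(s, low_hz, high_hz)
  X <- nuisance_design(s, motion, wm_mask, csf_mask, global_signal)
  list(series = regress_nuisance(s, X), mean_fd = fd, design = X)
}
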