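#' Seed-based functional connectivity map
#'
#' Averages the time series of the seed voxels (typically a surviving
#' cluster saved as a seed) and Pearson-correlates that mean series with
#' every in-mask voxel.
#'
#' @param series A preprocessed [bold_series()].
#' @param seed_voxels Non-empty integer vector of linear array indices,
#'   all inside the series' mask.
#' @return 3D array of correlations (0 outside the mask).
#' @export
seed_fc_map <- function(series, seed_voxels) {
  if (!length(seed_voxels)) stop("seed is empty")
  cols <- match(seed_voxels, series$mask$indices)
  if (anyNA(cols)) stop("seed voxels must lie inside the series mask")
  seed <- rowMeans(series$data[, cols, drop = FALSE])
  if (stats::sd(seed) == 0) stop("seed mean time series has zero variance")
  r <- suppressWarnings(drop(stats::cor(seed, series$data)))
  r[is.na(r)] <- 0                       # zero-variance voxels
  out <- array(0, series$grid$shape)
  out[series$mask$indices] <- r
  out
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, variance-stabilising for
#' correlation maps before group statistics. Values at `|r| >= 1` are
#' clipped to `1 - 1e-7` in magnitude with a warning.
#'
#' @param r Numeric vector or array of correlations.
#' @return Transformed values, same shape.
#' @export
fisher_z <- function(r) {
  clip <- 1 - 1e-7
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("correlations at |r| >= 1 clipped to ", format(clip))
    r[r >= 1] <- clip
    r[r <= -1] <- -clip
  }
  atanh(r)
}
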