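#' Parameters of the FCD computation
#'
#' @param r_threshold Connectional threshold on Pearson r (default 0.3);
#'   a pair contributes iff `r > r_threshold` (positive maps) or
#'   `r < -r_threshold` (negative maps), strictly.
#' @param radius_mm Long/short-range boundary on Euclidean mm distance
#'   between voxel centres (default 75); pairs at exactly `radius_mm` are
#'   short-range ("within"), strictly greater is long-range.
#' @param mode `"count"` (binary degree, default) or `"weighted"`
#'   (each suprathreshold pair contributes `|r|`).
#' @param smoothing_fwhm_mm Gaussian FWHM for [smooth_fcd_maps()]
#'   (default 4).
#' @return An object of class `fcd_params`.
#' @export
fcd_params <- function(r_threshold = 0.3, radius_mm = 75,
                       mode = c("count", "weighted"),
                       smoothing_fwhm_mm = 4) {
  mode <- match.arg(mode)
  if (r_threshold <= 0 || r_threshold >= 1)
    stop("'r_threshold' must lie in (0, 1)")
  if (radius_mm <= 0) stop("'radius_mm' must be positive")
  if (smoothing_fwhm_mm < 0) stop("'smoothing_fwhm_mm' must be >= 0")
  structure(list(r_threshold = r_threshold, radius_mm = radius_mm,
                 mode = mode, smoothing_fwhm_mm = smoothing_fwhm_mm),
            class = "fcd_params")
}

#' Four-way functional connectivity density maps
#'
#' For every analysis-mask voxel v, Pearson-correlates its time series with
#' every other analysis voxel u and accumulates suprathreshold pairs into
#' four degree maps by correlation sign and by the Euclidean mm distance
#' between voxel centres: long-range positive (`lpfcd`, dist > radius),
#' short-range positive (`spfcd`, dist <= radius), and their negative
#' counterparts (`lnfcd`, `snfcd`, stored as non-negative magnitudes).
#' Self-pairs are excluded. Pairwise work is blocked over voxels so memory
#' stays O(n_voxels * T + block^2); results are independent of `block_size`.
#'
#' Voxels with zero temporal variance are excluded from both sides of every
#' pair with a warning (their map values are 0).
#'
#' @param series Preprocessed [bold_series()].
#' @param params An [fcd_params()].
#' @param analysis_mask Optional [brain_mask()] (e.g. the gray-matter
#'   shell), a subset of the series' mask; defaults to the series' mask.
#' @param block_size Voxels per block (default 2048).
#' @return An object of class `fcd_maps`: `grid`, `mask`, `maps` (named
#'   list of four 3D arrays), `params`, `normalized = "raw"`, and
#'   `excluded` (linear indices of zero-variance voxels).
#' @export
compute_fcd <- function(series, params = fcd_params(), analysis_mask = NULL,
                        block_size = 2048L) {
  mask <- if (is.null(analysis_mask)) series$mask else analysis_mask
  if (!is.null(analysis_mask)) {
    stopifnot_same_grid(series$grid, analysis_mask$grid)
    cols <- match(analysis_mask$indices, series$mask$indices)
    if (anyNA(cols)) stop("analysis mask is not a subset of the series mask")
    X <- series$data[, cols, drop = FALSE]
  } else {
    X <- series$data
  }
  nt <- nrow(X)
  if (nt < 3L) stop("need at least 3 time points for correlation")

  sds <- apply(X, 2, stats::sd)
  ok <- sds > 0
  excluded <- mask$indices[!ok]
  if (length(excluded))
    warning(length(excluded),
            " zero-variance voxel(s) excluded from FCD computation")

  shape <- mask$grid$shape
  maps <- list(lpfcd = array(0, shape), lnfcd = array(0, shape),
               spfcd = array(0, shape), snfcd = array(0, shape))
  n_ok <- sum(ok)
  if (n_ok >= 2L) {
    Z <- scale(X[, ok, drop = FALSE])          # unit sample SD columns
    coords <- mask_coords_mm(mask)[ok, , drop = FALSE]
    ss <- rowSums(coords^2)
    keep_idx <- mask$indices[ok]
    acc <- matrix(0, n_ok, 4)                  # lp, ln, sp, sn per voxel
    weighted <- params$mode == "weighted"
    starts <- seq.int(1L, n_ok, by = as.integer(block_size))
    for (s0 in starts) {
      cols <- s0:min(s0 + block_size - 1L, n_ok)
      R <- crossprod(Z, Z[, cols, drop = FALSE]) / (nt - 1)
      D2 <- outer(ss, rep(1, length(cols))) +
        outer(rep(1, n_ok), ss[cols]) -
        2 * coords %*% t(coords[cols, , drop = FALSE])
      D <- sqrt(pmax(D2, 0))
      self <- cbind(cols, seq_along(cols))     # exclude self-pairs
      pos <- R > params$r_threshold
      neg <- R < -params$r_threshold
      pos[self] <- FALSE
      neg[self] <- FALSE
      long <- D > params$radius_mm
      w <- if (weighted) abs(R) else 1
      acc[cols, 1] <- acc[cols, 1] + colSums((pos & long) * w)
      acc[cols, 2] <- acc[cols, 2] + colSums((neg & long) * w)
      acc[cols, 3] <- acc[cols, 3] + colSums((pos & !long) * w)
      acc[cols, 4] <- acc[cols, 4] + colSums((neg & !long) * w)
    }
    maps$lpfcd[keep_idx] <- acc[, 1]
    maps$lnfcd[keep_idx] <- acc[, 2]
    maps$spfcd[keep_idx] <- acc[, 3]
    maps$snfcd[keep_idx] <- acc[, 4]
  }
  structure(list(grid = mask$grid, mask = mask, maps = maps,
                 params = params, normalized = "raw", excluded = excluded),
            class = "fcd_maps")
}

#' @export
print.fcd_maps <- function(x, ...) {
  cat("<fcd_maps> (", x$normalized, ") ", x$mask$n_voxels, " voxels, mode=",
      x$params$mode, "\n", sep = "")
  invisible(x)
}

# 1D Gaussian kernel matrix (n x n) for sigma in voxel units, truncated at
# 4.5 sigma; K[i, j] = g(i - j)
gauss_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- min(n - 1L, as.integer(ceiling(4.5 * sigma_vox)))
  off <- (-half):half
  g <- exp(-off^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (d in seq_along(off)) {
    o <- off[d]
    i <- seq.int(max(1, 1 - o), min(n, n - o))
    K[cbind(i + o, i)] <- g[d]
  }
  K
}

# separable convolution of a 3D array with per-axis Gaussian kernels
conv_gauss3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  K1 <- gauss_kernel_matrix(d[1], sigma_vox[1])
  m <- matrix(arr, d[1], d[2] * d[3])
  arr <- array(K1 %*% m, d)
  K2 <- gauss_kernel_matrix(d[2], sigma_vox[2])
  arr <- aperm(arr, c(2, 1, 3))
  m <- matrix(arr, d[2], d[1] * d[3])
  arr <- aperm(array(K2 %*% m, c(d[2], d[1], d[3])), c(2, 1, 3))
  K3 <- gauss_kernel_matrix(d[3], sigma_vox[3])
  arr <- aperm(arr, c(3, 1, 2))
  m <- matrix(arr, d[3], d[1] * d[2])
  aperm(array(K3 %*% m, c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Masked Gaussian smoothing of a 3D map
#'
#' Convolves the map with a Gaussian of the stated FWHM, with the kernel
#' renormalised over in-mask support at every voxel (out-of-mask values
#' never bleed in; a constant in-mask map is unchanged). `fwhm_mm = 0` is
#' the identity. Out-of-mask output is 0.
#'
#' @param map 3D numeric array on the mask's grid.
#' @param mask A [brain_mask()].
#' @param fwhm_mm Full width at half maximum in mm.
#' @return Smoothed 3D array.
#' @export
smooth_map <- function(map, mask, fwhm_mm) {
  if (!identical(dim(map), as.integer(mask$grid$shape)))
    stop("map shape does not match mask grid")
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) {
    out <- map
    out[!mask$flags] <- 0
    return(out)
  }
  sigma_vox <- (fwhm_mm / sqrt(8 * log(2))) / voxel_spacing(mask$grid)
  m <- ifelse(mask$flags, 1, 0)
  num <- conv_gauss3(map * m, sigma_vox)
  den <- conv_gauss3(m, sigma_vox)
  out <- array(0, dim(map))
  out[mask$flags] <- num[mask$flags] / den[mask$flags]
  out
}

#' Z-standardise a map over its mask
#'
#' Subtracts the in-mask mean and divides by the in-mask sample SD;
#' out-of-mask voxels are set to 0. This per-subject standardisation makes
#' FCD z scores comparable across subjects before group statistics.
#'
#' @param map 3D numeric array.
#' @param mask A [brain_mask()].
#' @return Standardised 3D array (in-mask mean 0, SD 1).
#' @export
zscore_map <- function(map, mask) {
  if (!identical(dim(map), as.integer(mask$grid$shape)))
    stop("map shape does not match mask grid")
  v <- map[mask$indices]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("in-mask standard deviation is zero")
  out <- array(0, dim(map))
  out[mask$indices] <- (v - mean(v)) / s
  out
}

#' Smooth all four FCD maps
#'
#' Applies [smooth_map()] with the parameter set's FWHM to each raw map and
#' marks the object `smoothed`.
#' @param fcd An `fcd_maps` object (raw).
#' @return An `fcd_maps` object with `normalized = "smoothed"`.
#' @export
smooth_fcd_maps <- function(fcd) {
  fcd$maps <- lapply(fcd$maps, smooth_map, mask = fcd$mask,
                     fwhm_mm = fcd$params$smoothing_fwhm_mm)
  fcd$normalized <- "smoothed"
  fcd
}

#' Z-standardise all four FCD maps
#'
#' Applies [zscore_map()] to each map (conventionally after smoothing) and
#' marks the object `zscored`.
#' @param fcd An `fcd_maps` object.
#' @return An `fcd_maps` object with `normalized = "zscored"`.
#' @export
zscore_fcd_maps <- function(fcd) {
  fcd$maps <- lapply(fcd$maps, zscore_map, mask = fcd$mask)
  fcd$normalized <- "zscored"
  fcd
}

#' Write the four FCD maps as one 4D volume
#'
#' Stacks lpfcd, lnfcd, spfcd, snfcd (in that order) along the fourth axis.
#' @param fcd An `fcd_maps` object.
#' @param path Output .nii / .nii.gz path.
#' @return `path`, invisibly.
#' @export
write_fcd_maps <- function(fcd, path) {
  arr <- array(0, c(fcd$grid$shape, 4L))
  for (k in 1:4) arr[, , , k] <- fcd$maps[[k]]
  write_volume(fcd$grid, arr, path)
}
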