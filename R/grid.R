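#' Spatial grid of a volumetric image
#'
#' A `volume_grid` couples the array dimensions of a 3D image with the 4x4
#' affine transform that maps 0-based voxel indices to millimetre (MNI-style)
#' coordinates of voxel centres. Every map, mask and time series in the
#' package carries (or refers to) one of these, and all stages require their
#' inputs to share a single grid: volumes are never resampled.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param affine Numeric 4x4 matrix; upper-left 3x3 block must be invertible,
#'   last row `(0, 0, 0, 1)`.
#' @return An object of class `volume_grid` with elements `shape`, `affine`
#'   and `voxel_volume_mm3` (absolute determinant of the 3x3 block).
#' @examples
#' g <- volume_grid(c(10, 10, 10), diag(c(3, 3, 3, 1)))
#' g$voxel_volume_mm3  # 27
#' @export
volume_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be three positive integers")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row of 'affine' must be (0, 0, 0, 1)")
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < .Machine$double.eps)
    stop("upper-left 3x3 block of 'affine' must be invertible")
  structure(
    list(shape = shape, affine = affine, voxel_volume_mm3 = abs(d)),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels, voxel volume ", format(x$voxel_volume_mm3), " mm^3\n", sep = "")
  invisible(x)
}

#' Physical voxel spacing along each axis
#'
#' Column norms of the affine's 3x3 block, in mm per voxel step.
#' @param grid A [volume_grid()].
#' @return Numeric length-3 vector.
#' @export
voxel_spacing <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' Check that two grids agree
#'
#' Shapes must match exactly and affines element-wise within `tol`.
#' @param a,b [volume_grid()] objects.
#' @param tol Numeric tolerance on affine elements.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
stopifnot_same_grid <- function(a, b, tol = 1e-4) {
  if (!identical(a$shape, b$shape))
    stop("grids differ in shape: ", paste(a$shape, collapse = "x"), " vs ",
         paste(b$shape, collapse = "x"))
  if (max(abs(a$affine - b$affine)) > tol)
    stop("grids differ in affine (max |diff| = ",
         format(max(abs(a$affine - b$affine))), ")")
  invisible(TRUE)
}

#' Map voxel indices to millimetre coordinates
#'
#' Applies the grid affine to 0-based voxel indices. Reported coordinates
#' throughout the package (cluster peaks, pair distances) come through here.
#'
#' @param grid A [volume_grid()].
#' @param index Integer triple (0-based), or an n x 3 matrix of triples.
#' @return Numeric triple, or an n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(grid, index) {
  idx <- if (is.matrix(index)) index else matrix(index, nrow = 1)
  if (ncol(idx) != 3L) stop("'index' must have three columns")
  lo <- sweep(idx, 2, grid$shape, "-")
  if (any(idx < 0) || any(lo >= 0))
    stop("voxel index out of range for grid of shape ",
         paste(grid$shape, collapse = "x"))
  mm <- cbind(idx, 1) %*% t(grid$affine)
  mm <- mm[, 1:3, drop = FALSE]
  if (is.matrix(index)) mm else drop(mm)
}

#' Map millimetre coordinates to (fractional) voxel indices
#'
#' Inverse of [voxel_to_mm()]; returns fractional 0-based indices, not
#' rounded, so callers can decide how to snap to the grid.
#' @param grid A [volume_grid()].
#' @param mm Numeric triple or n x 3 matrix.
#' @return Numeric triple or n x 3 matrix of 0-based indices.
#' @export
mm_to_voxel <- function(grid, mm) {
  pts <- if (is.matrix(mm)) mm else matrix(mm, nrow = 1)
  if (ncol(pts) != 3L) stop("'mm' must have three columns")
  inv <- solve(grid$affine)
  idx <- cbind(pts, 1) %*% t(inv)
  idx <- idx[, 1:3, drop = FALSE]
  if (is.matrix(mm)) idx else drop(idx)
}

#' Binary analysis mask on a grid
#'
#' @param grid A [volume_grid()].
#' @param flags Logical 3D array with `dim(flags) == grid$shape`.
#' @return An object of class `brain_mask` with `grid`, `flags`, `n_voxels`
#'   and `indices`, the linear (1-based, column-major) array indices of the
#'   in-mask voxels. This column-major scan order -- first axis fastest --
#'   is the fixed voxel ordering every module shares.
#' @export
brain_mask <- function(grid, flags) {
  storage.mode(flags) <- "logical"
  if (!identical(dim(flags), as.integer(grid$shape)))
    stop("mask flags shape does not match grid shape")
  if (anyNA(flags)) stop("mask flags must not contain NA")
  idx <- which(flags)
  if (length(idx) < 1L) stop("mask must contain at least one voxel")
  structure(
    list(grid = grid, flags = flags, n_voxels = length(idx), indices = idx),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("<brain_mask> ", x$n_voxels, " voxels on ",
      paste(x$grid$shape, collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

#' 0-based voxel index triples of in-mask voxels, in scan order
#' @param mask A [brain_mask()].
#' @return n x 3 integer matrix.
#' @export
mask_voxel_indices <- function(mask) {
  arrayInd(mask$indices, mask$grid$shape) - 1L
}

#' Millimetre coordinates of in-mask voxel centres, in scan order
#' @param mask A [brain_mask()].
#' @return n x 3 numeric matrix.
#' @export
mask_coords_mm <- function(mask) {
  voxel_to_mm(mask$grid, mask_voxel_indices(mask))
}

#' Masked BOLD time series
#'
#' One subject's 4D series reduced to its in-mask voxels. `data` is a
#' T x n matrix: rows are time points, columns are voxels in the mask's
#' column-major scan order (see [brain_mask()]).
#'
#' @param mask A [brain_mask()].
#' @param data T x n numeric matrix, `n == mask$n_voxels`, all finite, T >= 2.
#' @param tr_seconds Positive scalar repetition time.
#' @return An object of class `bold_series` with `grid`, `mask`, `data`,
#'   `tr_seconds` and `n_timepoints`.
#' @export
bold_series <- function(mask, data, tr_seconds) {
  data <- as.matrix(data)
  if (ncol(data) != mask$n_voxels)
    stop("data has ", ncol(data), " columns but mask has ", mask$n_voxels,
         " voxels")
  if (nrow(data) < 2L) stop("need at least 2 time points")
  if (!all(is.finite(data))) stop("BOLD data contains non-finite values")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("'tr_seconds' must be a positive scalar")
  structure(
    list(grid = mask$grid, mask = mask, data = data,
         tr_seconds = tr_seconds, n_timepoints = nrow(data)),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  cat("<bold_series> ", x$n_timepoints, " time points x ", x$mask$n_voxels,
      " voxels, TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' Replace the data matrix of a series, keeping its frame
#' @param series A [bold_series()].
#' @param data New T' x n matrix.
#' @return A new [bold_series()].
#' @keywords internal
series_with_data <- function(series, data) {
  bold_series(series$mask, data, series$tr_seconds)
}

#' Extract a 4D array from a masked series (zeros outside the mask)
#' @param series A [bold_series()].
#' @return Array of dim `c(grid$shape, T)`.
#' @export
series_to_array <- function(series) {
  g <- series$grid
  out <- array(0, c(g$shape, series$n_timepoints))
  nvol <- prod(g$shape)
  for (t in seq_len(series$n_timepoints))
    out[(t - 1L) * nvol + series$mask$indices] <- series$data[t, ]
  out
}

#' Build a masked series from a 4D array
#' @param mask A [brain_mask()].
#' @param arr 4D array on the mask's grid, time last.
#' @param tr_seconds Repetition time in seconds.
#' @return A [bold_series()].
#' @export
series_from_array <- function(mask, arr, tr_seconds) {
  if (length(dim(arr)) != 4L) stop("expected a 4D array")
  if (!identical(dim(arr)[1:3], as.integer(mask$grid$shape)))
    stop("array spatial shape does not match mask grid")
  nt <- dim(arr)[4]
  nvol <- prod(dim(arr)[1:3])
  dat <- matrix(0, nt, mask$n_voxels)
  for (t in seq_len(nt))
    dat[t, ] <- arr[(t - 1L) * nvol + mask$indices]
  bold_series(mask, dat, tr_seconds)
}
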