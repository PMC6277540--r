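#' Voxelwise general-linear-model t map
#'
#' Fits the same subject-level design at every in-mask voxel by ordinary
#' least squares and returns the t statistic for a single contrast of the
#' coefficients, with error degrees of freedom `n - rank(design)`.
#' Residual maps are retained for random-field smoothness estimation.
#'
#' Typical designs: one-sample (intercept only, contrast on the intercept --
#' tests the map mean against 0) and two-sample group comparison with
#' nuisance covariates (age, sex, education, BMI, mean framewise
#' displacement, blood measures), contrast on the group column.
#'
#' @param maps n_voxels x n_subjects numeric matrix in mask scan order
#'   (e.g. stacked z-scored FCD maps).
#' @param design n_subjects x p design matrix (include the intercept
#'   yourself; see [group_design()]).
#' @param contrast Length-p numeric contrast vector.
#' @param mask A [brain_mask()] whose voxel count matches `nrow(maps)`.
#' @param contrast_name Label stored with the map.
#' @return An object of class `stat_map`: `grid`, `mask`, `t` (3D array, 0
#'   outside the mask), `df`, `contrast_name`, `residuals`
#'   (n_voxels x n_subjects), `fwhm_mm` (per-axis residual smoothness) and
#'   `resels`.
#' @export
glm_t_map <- function(maps, design, contrast, mask,
                      contrast_name = "contrast") {
  maps <- as.matrix(maps)
  design <- as.matrix(design)
  n <- ncol(maps)
  if (nrow(design) != n)
    stop("design has ", nrow(design), " rows but maps have ", n, " subjects")
  if (nrow(maps) != mask$n_voxels)
    stop("maps have ", nrow(maps), " rows but mask has ", mask$n_voxels,
         " voxels")
  if (length(contrast) != ncol(design))
    stop("contrast length must equal number of design columns")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    cn <- colnames(design)
    if (is.null(cn)) cn <- paste0("col", seq_len(ncol(design)))
    stop("design is rank deficient; collinear columns: ",
         paste(cn[qrX$pivot[(qrX$rank + 1):ncol(design)]], collapse = ", "))
  }
  df <- n - qrX$rank
  if (df < 1L) stop("no error degrees of freedom (n <= rank(design))")

  unpivot <- order(qrX$pivot)
  xtx_inv <- chol2inv(qr.R(qrX))[unpivot, unpivot, drop = FALSE]
  coef <- maps %*% design %*% xtx_inv            # n_voxels x p
  fitted <- coef %*% t(design)
  res <- maps - fitted
  sigma2 <- rowSums(res^2) / df
  cvar <- drop(t(contrast) %*% xtx_inv %*% contrast)
  tval <- drop(coef %*% contrast) / sqrt(pmax(sigma2 * cvar,
                                              .Machine$double.xmin))
  # voxels fitted exactly (zero residual variance up to round-off) carry no
  # evidence either way
  tval[sigma2 <= 1e-20 * pmax(rowMeans(maps^2), 1e-300)] <- 0
  tmap <- array(0, mask$grid$shape)
  tmap[mask$indices] <- tval

  sm <- estimate_smoothness(res, mask)
  structure(list(grid = mask$grid, mask = mask, t = tmap, df = df,
                 contrast_name = contrast_name, residuals = res,
                 fwhm_mm = sm$fwhm_mm, resels = sm$resels),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> '", x$contrast_name, "', df = ", x$df,
      ", residual FWHM = ", paste(round(x$fwhm_mm, 2), collapse = "/"),
      " mm, ", round(x$resels, 1), " resels\n", sep = "")
  invisible(x)
}

#' Group-comparison design matrix
#'
#' Builds `[intercept, group indicator, covariates...]` from a subject
#' table. The group indicator is 1 for `levels[2]`; the usual contrast
#' `c(0, 1, 0, ...)` then tests `levels[2] - levels[1]` (e.g. patient minus
#' control).
#'
#' @param table A subject table (see [load_subject_table()]).
#' @param covariates Character vector of column names to adjust for.
#' @param levels Group levels, reference first; defaults to
#'   `c("control", "patient")` when present, else sorted levels.
#' @return List with `design` (n x p matrix), `contrast` (group contrast
#'   vector) and `levels`.
#' @export
group_design <- function(table, covariates = character(), levels = NULL) {
  grp <- as.character(table$group)
  if (is.null(levels)) {
    levels <- sort(unique(grp))
    if (all(c("control", "patient") %in% levels))
      levels <- c("control", "patient")
  }
  if (!all(grp %in% levels)) stop("unknown group labels")
  X <- cbind(intercept = 1, group = as.numeric(grp == levels[2]))
  for (cv in covariates) {
    if (!cv %in% names(table)) stop("covariate '", cv, "' not in table")
    v <- as.numeric(table[[cv]])
    if (any(!is.finite(v))) stop("covariate '", cv, "' has non-finite values")
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  list(design = X, contrast = c(0, 1, rep(0, length(covariates))),
       levels = levels)
}

#' Residual smoothness and resel count
#'
#' Estimates the per-axis Gaussian FWHM of the residual field from the
#' variance of spatial first differences of the voxelwise-normalised
#' residuals (for a unit-variance Gaussian field with derivative variance
#' lambda per axis, FWHM = sqrt(4 log 2 / lambda) voxels). The resel count
#' is the mask volume divided by the product of the per-axis FWHMs.
#'
#' @param residuals n_voxels x n_subjects residual matrix in mask scan
#'   order (n_subjects >= 2).
#' @param mask A [brain_mask()].
#' @param min_fwhm_vox Lower clamp on the per-axis estimate, in voxels
#'   (default 0.5).
#' @return List with `fwhm_mm` (length 3), `fwhm_vox`, `resels`.
#' @export
estimate_smoothness <- function(residuals, mask, min_fwhm_vox = 0.5) {
  residuals <- as.matrix(residuals)
  if (ncol(residuals) < 2L) stop("need at least 2 residual maps")
  if (nrow(residuals) != mask$n_voxels)
    stop("residual rows must match mask voxel count")
  norms <- sqrt(rowSums(residuals^2))
  if (any(norms == 0)) stop("constant (all-zero) residuals at some voxels")
  U <- residuals / norms

  shape <- mask$grid$shape
  lam <- numeric(3)
  for (ax in 1:3) {
    step <- c(1L, shape[1], shape[1] * shape[2])[ax]
    vox <- arrayInd(mask$indices, shape)
    ok <- vox[, ax] < shape[ax]
    nb <- mask$indices[ok] + step
    inmask <- !is.na(match(nb, mask$indices))
    a <- match(mask$indices[ok][inmask], mask$indices)
    b <- match(nb[inmask], mask$indices)
    if (!length(a)) stop("mask has no interior voxel pairs along axis ", ax)
    d <- U[b, , drop = FALSE] - U[a, , drop = FALSE]
    lam[ax] <- mean(rowSums(d^2))
  }
  fwhm_vox <- pmax(sqrt(4 * log(2) / lam), min_fwhm_vox)
  fwhm_mm <- fwhm_vox * voxel_spacing(mask$grid)
  resels <- mask$n_voxels * mask$grid$voxel_volume_mm3 / prod(fwhm_mm)
  list(fwhm_mm = fwhm_mm, fwhm_vox = fwhm_vox, resels = resels)
}
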