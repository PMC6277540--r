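#' Mean cluster value per subject
#'
#' Extracts, for each subject, the mean of that subject's (z-scored) map
#' over a cluster's voxels -- the scalar entering brain-behaviour
#' correlation.
#'
#' @param maps n_voxels x n_subjects matrix in mask scan order, or a list
#'   of 3D arrays.
#' @param cluster_voxels Non-empty integer vector of linear array indices
#'   inside the mask.
#' @param mask A [brain_mask()] (required to locate the cluster rows when
#'   `maps` is a matrix).
#' @return Numeric vector, one score per subject.
#' @export
extract_cluster_scores <- function(maps, cluster_voxels, mask) {
  if (!length(cluster_voxels)) stop("empty cluster")
  if (is.list(maps) && !is.matrix(maps))
    maps <- vapply(maps, function(m) m[mask$indices], numeric(mask$n_voxels))
  rows <- match(cluster_voxels, mask$indices)
  if (anyNA(rows)) stop("cluster voxels must lie inside the mask")
  colMeans(maps[rows, , drop = FALSE])
}

#' Covariate-adjusted (partial) Pearson correlation
#'
#' Residualises `x` and `y` on `[intercept, covariates]` and Pearson-
#' correlates the residuals; the p-value uses the t transform with
#' `df = n - k - 2` where k is the number of covariates. With no
#' covariates this reduces to the plain Pearson correlation and test.
#'
#' @param x,y Numeric vectors of equal length n.
#' @param covariates Optional n x k numeric matrix or data frame.
#' @param method `"pearson"` (default) or `"spearman"` (ranks are taken
#'   before residualisation).
#' @return List of class `association_result`: `n`, `k`, `partial_r`,
#'   `p_value`, `df`, `method`.
#' @export
partial_pearson <- function(x, y, covariates = NULL,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  C <- if (is.null(covariates)) matrix(nrow = n, ncol = 0)
       else as.matrix(covariates)
  if (nrow(C) != n) stop("covariates must have one row per subject")
  k <- ncol(C)
  if (n <= k + 2) stop("need n > number of covariates + 2 (n = ", n,
                       ", k = ", k, ")")
  if (any(!is.finite(x)) || any(!is.finite(y)) || (k > 0 && any(!is.finite(C))))
    stop("inputs must be finite")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  X <- cbind(1, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("covariate matrix is rank deficient")
  rx <- qr.resid(qrX, x)
  ry <- qr.resid(qrX, y)
  if (stats::sd(rx) <= 1e-10 * (stats::sd(x) + 1e-300) ||
      stats::sd(ry) <= 1e-10 * (stats::sd(y) + 1e-300))
    stop("zero residual variance after adjustment")
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  structure(list(n = n, k = k, partial_r = r, p_value = min(p, 1), df = df,
                 method = method),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("partial r = ", round(x$partial_r, 3), ", p = ",
      signif(x$p_value, 3), " (n = ", x$n, ", ", x$k,
      " covariates, ", x$method, ")\n", sep = "")
  invisible(x)
}

#' Brain-behaviour association over clusters and measures
#'
#' For every (cluster, measure) pair: extract per-subject mean z scores
#' over the cluster, then partial-Pearson-correlate them with the measure
#' adjusting for the covariates. Restricted to the patient group by
#' default, matching the convention of correlating within the clinical
#' group only. P-values are reported uncorrected by default; `adjust =
#' "BH"` adds a Benjamini-Hochberg column.
#'
#' @param maps n_voxels x n_subjects matrix (all subjects, table order).
#' @param mask A [brain_mask()].
#' @param clusters A `cluster_table` from [grf_cluster_threshold()] (its
#'   `members` attribute supplies the voxel sets).
#' @param table Subject table aligned with the columns of `maps`.
#' @param measures Character vector of score columns to test.
#' @param covariates Character vector of adjustment columns.
#' @param group Restrict to this group label (default "patient"; NULL for
#'   all subjects).
#' @param adjust "none" (default) or "BH".
#' @return Data frame: `cluster`, `measure`, `n`, `partial_r`, `p_value`
#'   (and `p_adj` if requested).
#' @export
associate_clusters <- function(maps, mask, clusters, table, measures,
                               covariates = character(),
                               group = "patient", adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  members <- attr(clusters, "members")
  if (is.null(members) || nrow(clusters) == 0L)
    return(data.frame(cluster = integer(), measure = character(),
                      n = integer(), partial_r = numeric(),
                      p_value = numeric()))
  sel <- if (is.null(group)) rep(TRUE, nrow(table))
         else as.character(table$group) == group
  C <- if (length(covariates))
    as.matrix(as.data.frame(table[sel, covariates, drop = FALSE]))
  else NULL
  out <- NULL
  for (ci in seq_len(nrow(clusters))) {
    scores <- extract_cluster_scores(maps[, sel, drop = FALSE],
                                     members[[ci]], mask)
    for (m in measures) {
      res <- partial_pearson(scores, as.numeric(table[[m]][sel]), C)
      out <- rbind(out, data.frame(cluster = clusters$label[ci], measure = m,
                                   n = res$n, partial_r = res$partial_r,
                                   p_value = res$p_value))
    }
  }
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
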