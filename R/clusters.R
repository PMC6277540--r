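#' Connected-component labelling of a binary 3D map
#'
#' Labels connected suprathreshold voxels under 6-, 18- or 26-neighbour
#' connectivity. Label order is deterministic: components sorted by size
#' (descending), ties broken by the lexicographically smallest member voxel
#' index triple.
#'
#' @param flags Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return List of integer vectors of linear (column-major) array indices,
#'   one per component; empty list if no voxel is set.
#' @export
label_clusters <- function(flags, connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  shape <- dim(flags)
  if (length(shape) != 3L) stop("expected a 3D array")
  idx <- which(flags)
  if (!length(idx)) return(list())

  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  off <- off[nz > 0 & switch(as.character(connectivity),
                             "6" = nz == 1, "18" = nz <= 2, "26" = nz <= 3), ,
             drop = FALSE]

  vox <- arrayInd(idx, shape)
  inset <- array(0L, shape)        # position of each set voxel in `idx`
  inset[idx] <- seq_along(idx)
  comp <- integer(length(idx))     # 0 = unvisited
  ncomp <- 0L
  for (s in seq_along(idx)) {
    if (comp[s] > 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      v <- vox[cur, ]
      nb <- sweep(off, 2, v, "+")
      okb <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nb <- nb[okb, , drop = FALSE]
      lin <- nb[, 1] + shape[1] * (nb[, 2] - 1L + shape[2] * (nb[, 3] - 1L))
      pos <- inset[lin]
      pos <- pos[pos > 0L]
      pos <- pos[comp[pos] == 0L]
      if (length(pos)) {
        comp[pos] <- ncomp
        queue <- c(queue, pos)
      }
    }
  }
  comps <- unname(split(idx, comp))
  sizes <- lengths(comps)
  first <- vapply(comps, min, numeric(1))   # column-major min = lexicographic
  comps[order(-sizes, first)]
}

# Euler-characteristic density (3D) of a t field with `df` degrees of
# freedom at threshold u, in resel units
ec_density_t3 <- function(u, df) {
  (4 * log(2))^(3 / 2) / (2 * pi)^2 *
    ((df - 1) / df * u^2 - 1) * (1 + u^2 / df)^(-(df - 1) / 2)
}

#' Random-field cluster-level p-value
#'
#' Classical Gaussian random-field cluster inference for a 3D t field: the
#' expected number of suprathreshold clusters comes from the
#' Euler-characteristic density at the cluster-forming threshold times the
#' resel count; the expected cluster size is the expected suprathreshold
#' volume over the expected cluster count; the probability that a cluster
#' reaches `k` voxels follows the exponential form
#' `exp(-beta * k^(2/3))` with `beta = (gamma(5/2) / expected size)^(2/3)`;
#' and the familywise cluster p is
#' `1 - exp(-E[clusters] * P(size >= k))`.
#'
#' @param k_voxels Cluster extent in voxels (may be a vector).
#' @param u Cluster-forming t threshold (one-sided).
#' @param df Error degrees of freedom.
#' @param resels Resel count of the search region.
#' @param n_mask_voxels Voxels in the search region.
#' @return Numeric vector of corrected cluster p-values in (0, 1].
#' @export
grf_cluster_p <- function(k_voxels, u, df, resels, n_mask_voxels) {
  em <- max(resels * ec_density_t3(u, df), 1e-12)   # expected cluster count
  en <- n_mask_voxels * stats::pt(u, df, lower.tail = FALSE)
  n_bar <- max(en / em, .Machine$double.eps)        # expected size, voxels
  beta <- (gamma(5 / 2) / n_bar)^(2 / 3)
  p_ge_k <- exp(-beta * k_voxels^(2 / 3))
  pmin(1, pmax(1 - exp(-em * p_ge_k), .Machine$double.xmin))
}

#' Tabulate one cluster of a t map
#'
#' Peak is the member voxel with maximal |t|; ties go to the
#' lexicographically smallest mm coordinate. Extent in mm^3 is the voxel
#' count times the grid's voxel volume.
#'
#' @param stat A `stat_map` (see [glm_t_map()]).
#' @param voxels Non-empty integer vector of linear array indices.
#' @return One-row data frame: `extent_voxels`, `extent_mm3`, `peak_x`,
#'   `peak_y`, `peak_z` (mm), `peak_t`.
#' @export
tabulate_cluster <- function(stat, voxels) {
  if (!length(voxels)) stop("empty cluster")
  tvals <- stat$t[voxels]
  mm <- voxel_to_mm(stat$grid, arrayInd(voxels, stat$grid$shape) - 1L)
  best <- which(abs(tvals) == max(abs(tvals)))
  if (length(best) > 1L)
    best <- best[order(mm[best, 1], mm[best, 2], mm[best, 3])[1]]
  data.frame(extent_voxels = length(voxels),
             extent_mm3 = length(voxels) * stat$grid$voxel_volume_mm3,
             peak_x = mm[best, 1], peak_y = mm[best, 2], peak_z = mm[best, 3],
             peak_t = tvals[best])
}

#' Gaussian random-field cluster thresholding
#'
#' Forms clusters of voxels exceeding the one-sided t quantile at
#' `voxel_p`, computes each cluster's familywise random-field p-value
#' ([grf_cluster_p()]) and keeps clusters with `cluster_p < cluster_p`
#' threshold. `tail = "both"` (the default) runs independent positive and
#' negative one-sided passes and merges the tables with signed peaks.
#'
#' @param stat A `stat_map`.
#' @param voxel_p Cluster-forming (uncorrected, one-sided) voxel p
#'   (default 0.01).
#' @param cluster_p Familywise cluster significance level (default 0.05).
#' @param tail "positive", "negative" or "both".
#' @param connectivity Cluster connectivity: 6, 18 or 26 (default 26).
#' @return Data frame of class `cluster_table`, one row per surviving
#'   cluster: `label`, `tail`, `extent_voxels`, `extent_mm3`, peak mm
#'   coordinates, `peak_t`, `cluster_p`; member voxels in
#'   `attr(, "members")` (list of linear index vectors). Zero rows when
#'   nothing survives.
#' @export
grf_cluster_threshold <- function(stat, voxel_p = 0.01, cluster_p = 0.05,
                                  tail = c("both", "positive", "negative"),
                                  connectivity = 26L) {
  tail <- match.arg(tail)
  if (voxel_p <= 0 || voxel_p >= 1) stop("'voxel_p' must lie in (0, 1)")
  if (cluster_p <= 0 || cluster_p >= 1) stop("'cluster_p' must lie in (0, 1)")
  u <- stats::qt(voxel_p, stat$df, lower.tail = FALSE)

  one_pass <- function(sign_label) {
    field <- if (sign_label == "positive") stat$t else -stat$t
    flags <- array(FALSE, stat$grid$shape)
    flags[stat$mask$indices] <- field[stat$mask$indices] > u
    comps <- label_clusters(flags, connectivity)
    if (!length(comps))
      return(list(rows = NULL, members = list()))
    rows <- do.call(rbind, lapply(comps, tabulate_cluster, stat = stat))
    rows$cluster_p <- grf_cluster_p(rows$extent_voxels, u, stat$df,
                                    stat$resels, stat$mask$n_voxels)
    rows$tail <- sign_label
    keep <- rows$cluster_p < cluster_p
    list(rows = rows[keep, , drop = FALSE], members = comps[keep])
  }

  passes <- switch(tail, both = c("positive", "negative"), tail)
  rows <- NULL; members <- list()
  for (p in passes) {
    res <- one_pass(p)
    if (!is.null(res$rows) && nrow(res$rows)) {
      rows <- rbind(rows, res$rows)
      members <- c(members, res$members)
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(label = integer(), tail = character(),
                       extent_voxels = integer(), extent_mm3 = numeric(),
                       peak_x = numeric(), peak_y = numeric(),
                       peak_z = numeric(), peak_t = numeric(),
                       cluster_p = numeric())
  } else {
    ord <- order(-rows$extent_voxels, rows$peak_x, rows$peak_y, rows$peak_z)
    rows <- rows[ord, , drop = FALSE]
    members <- members[ord]
    rows <- cbind(label = seq_len(nrow(rows)), rows)
    rows <- rows[, c("label", "tail", "extent_voxels", "extent_mm3",
                     "peak_x", "peak_y", "peak_z", "peak_t", "cluster_p")]
    rownames(rows) <- NULL
  }
  attr(rows, "members") <- members
  attr(rows, "threshold_t") <- u
  class(rows) <- c("cluster_table", "data.frame")
  rows
}
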