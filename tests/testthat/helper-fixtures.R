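# Shared fixtures and independent oracles used across the test files.

# isotropic grid whose mm origin sits at voxel (0,0,0) unless shifted
tiny_grid <- function(shape, voxel_mm = 3, origin_mm = c(0, 0, 0)) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- origin_mm
  volume_grid(shape, aff)
}

# full-cube mask over a grid
cube_mask <- function(grid) {
  brain_mask(grid, array(TRUE, grid$shape))
}

# small two-block cohort spec on an 8^3 phantom, for fast Monte-Carlo runs
tiny_cohort_spec <- function(n_per_group = 4L, n_timepoints = 20L,
                             seed = 1L, coupling = 0.28, ...) {
  ph <- make_phantom_mask(c(8L, 8L, 8L), 3)
  ctr <- as.integer(round((ph$grid$shape - 1) / 2))
  blocks <- list(
    a = cube_block(ph$grid, c(1L, ctr[2], ctr[3]), 0L, ph$mask),
    b = cube_block(ph$grid, c(ph$grid$shape[1] - 2L, ctr[2], ctr[3]), 0L,
                   ph$mask)
  )
  net <- network_spec(blocks, weights = 1,
                      couplings = data.frame(parent = "a", child = "b",
                                             coupling = coupling))
  cohort_spec(n_per_group = n_per_group, grid = ph$grid, mask = ph$mask,
              network = net, n_timepoints = n_timepoints, seed = seed,
              group_effect = list(block = "b", direction = "raise",
                                  delta = 0.30), ...)
}

# O(N^2) brute-force FCD oracle: full masked correlation matrix, every pair
# binned by sign and centroid distance
fcd_oracle <- function(series, params, analysis_mask = NULL) {
  mask <- if (is.null(analysis_mask)) series$mask else analysis_mask
  X <- if (is.null(analysis_mask)) series$data else
    series$data[, match(analysis_mask$indices, series$mask$indices),
                drop = FALSE]
  sds <- apply(X, 2, sd)
  ok <- sds > 0
  R <- suppressWarnings(cor(X))
  coords <- mask_coords_mm(mask)
  n <- ncol(X)
  shape <- mask$grid$shape
  maps <- list(lpfcd = array(0, shape), lnfcd = array(0, shape),
               spfcd = array(0, shape), snfcd = array(0, shape))
  for (v in seq_len(n)) {
    if (!ok[v]) next
    for (u in seq_len(n)) {
      if (u == v || !ok[u]) next
      r <- R[v, u]
      d <- sqrt(sum((coords[v, ] - coords[u, ])^2))
      w <- if (params$mode == "weighted") abs(r) else 1
      tgt <- if (r > params$r_threshold) {
        if (d > params$radius_mm) "lpfcd" else "spfcd"
      } else if (r < -params$r_threshold) {
        if (d > params$radius_mm) "lnfcd" else "snfcd"
      } else NA
      if (!is.na(tgt)) maps[[tgt]][mask$indices[v]] <-
          maps[[tgt]][mask$indices[v]] + w
    }
  }
  maps
}

# recursive flood-fill connected components oracle (stack-free via repeat
# dilation over an explicit neighbour list; independent of the BFS in the
# package)
floodfill_oracle <- function(flags, connectivity) {
  shape <- dim(flags)
  idx <- which(flags)
  if (!length(idx)) return(list())
  vox <- arrayInd(idx, shape)
  n <- length(idx)
  # adjacency via pairwise Chebyshev/Manhattan tests (small n only)
  lab <- seq_len(n)
  adj <- function(i, j) {
    d <- abs(vox[i, ] - vox[j, ])
    if (max(d) > 1) return(FALSE)
    s <- sum(d)
    switch(as.character(connectivity),
           "6" = s == 1, "18" = s >= 1 && s <= 2, "26" = s >= 1)
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (lab[i] != lab[j] && adj(i, j)) {
        m <- min(lab[i], lab[j])
        lab[lab == lab[i] | lab == lab[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comps <- split(idx, lab)
  names(comps) <- NULL
  comps
}

# canonical form of a component list for set comparison
canon_components <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, numeric(1)))]
}

# direct-space Gaussian convolution oracle with masked renormalisation,
# separable product kernel, no truncation
smooth_oracle <- function(map, mask, fwhm_mm) {
  sigma <- fwhm_mm / sqrt(8 * log(2))
  coords <- mask_coords_mm(mask)
  vals <- map[mask$indices]
  out <- array(0, dim(map))
  for (v in seq_len(mask$n_voxels)) {
    d2 <- rowSums(sweep(coords, 2, coords[v, ])^2)
    w <- exp(-d2 / (2 * sigma^2))
    out[mask$indices[v]] <- sum(w * vals) / sum(w)
  }
  out
}

# Moore-Penrose pseudo-inverse via SVD (oracle for least-squares residuals)
pinv <- function(X, tol = 1e-12) {
  s <- svd(X)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
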