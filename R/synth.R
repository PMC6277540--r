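#' Ellipsoidal phantom brain mask
#'
#' Builds an isotropic grid whose affine is centred so that mm coordinate
#' (0, 0, 0) sits at the grid centre, and a "brain" mask of all voxels whose
#' centres fall inside an axis-aligned ellipsoid with semi-axes
#' `fill * (shape - 1) / 2` voxels.
#'
#' @param shape Integer triple, each >= 4.
#' @param voxel_mm Isotropic voxel size in mm (default 3, the acquisition
#'   resolution emulated throughout).
#' @param fill Fraction of the half-extent used as ellipsoid semi-axis.
#' @return List with `grid` ([volume_grid()]) and `mask` ([brain_mask()]).
#' @export
make_phantom_mask <- function(shape, voxel_mm = 3, fill = 0.95) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("'shape' must be three integers, each >= 4")
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -voxel_mm * (shape - 1) / 2
  grid <- volume_grid(shape, aff)
  semi <- pmax(fill * (shape - 1) / 2, 0.51)
  e2 <- phantom_radius2(shape, semi)
  list(grid = grid, mask = brain_mask(grid, e2 <= 1))
}

# squared normalised ellipsoid radius of every voxel centre (voxel units)
phantom_radius2 <- function(shape, semi) {
  ctr <- (shape - 1) / 2
  gx <- (seq_len(shape[1]) - 1 - ctr[1]) / semi[1]
  gy <- (seq_len(shape[2]) - 1 - ctr[2]) / semi[2]
  gz <- (seq_len(shape[3]) - 1 - ctr[3]) / semi[3]
  outer(outer(gx^2, gy^2, "+"), gz^2, "+")
}

#' Concentric tissue compartments of the phantom
#'
#' Splits the ellipsoidal brain into three shells by normalised radius:
#' a central "CSF" core (radius < 0.3), a "white matter" shell
#' (0.3 <= radius < 0.55) and an outer "gray matter" shell. The gray-matter
#' mask is the analysis mask for FCD; the inner compartments supply the
#' tissue nuisance signals.
#'
#' @param shape,voxel_mm,fill As in [make_phantom_mask()].
#' @return List with `grid`, `brain`, `gm`, `wm`, `csf` masks.
#' @export
make_phantom_compartments <- function(shape, voxel_mm = 3, fill = 0.95) {
  ph <- make_phantom_mask(shape, voxel_mm, fill)
  shape <- ph$grid$shape
  semi <- pmax(fill * (shape - 1) / 2, 0.51)
  r <- sqrt(phantom_radius2(shape, semi))
  list(grid = ph$grid, brain = ph$mask,
       gm  = brain_mask(ph$grid, r <= 1 & r >= 0.55),
       wm  = brain_mask(ph$grid, r < 0.55 & r >= 0.3),
       csf = brain_mask(ph$grid, r < 0.3))
}

#' Cubic block of voxel indices
#'
#' Linear (column-major) grid indices of the cube of half-width `half`
#' around a 0-based centre voxel, optionally intersected with a mask.
#' @param grid A [volume_grid()].
#' @param center 0-based voxel triple.
#' @param half Non-negative integer half-width.
#' @param mask Optional [brain_mask()]; out-of-mask voxels are dropped.
#' @return Integer vector of linear indices.
#' @export
cube_block <- function(grid, center, half = 1L, mask = NULL) {
  rng <- lapply(1:3, function(a)
    max(0L, center[a] - half):min(grid$shape[a] - 1L, center[a] + half))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  idx <- 1L + g[, 1] + grid$shape[1] * (g[, 2] + grid$shape[2] * g[, 3])
  if (!is.null(mask)) idx <- idx[mask$flags[idx]]
  sort(idx)
}

#' Planted block-network specification
#'
#' Blocks are disjoint sets of voxels sharing a latent signal; coupled block
#' pairs share a fraction of their latents. Couplings are directed
#' parent -> child edges forming a forest, so each child's latent is
#' `coupling * parent latent + sqrt(1 - coupling^2) * innovation`, giving the
#' pair a latent correlation exactly equal to `coupling`.
#'
#' @param blocks Named list of integer vectors (linear grid indices).
#' @param weights Numeric vector in `[0, 1]`, one shared-signal weight per
#'   block (recycled if length 1).
#' @param couplings Data frame with columns `parent`, `child` (block names)
#'   and `coupling` in `[-1, 1]`.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(blocks, weights = 1, couplings = NULL) {
  if (is.null(names(blocks)) || anyDuplicated(names(blocks)))
    stop("'blocks' must be a uniquely named list")
  all_idx <- unlist(blocks)
  if (anyDuplicated(all_idx)) stop("blocks must be disjoint")
  weights <- rep_len(weights, length(blocks))
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  if (is.null(couplings))
    couplings <- data.frame(parent = character(), child = character(),
                            coupling = numeric())
  stopifnot(all(c("parent", "child", "coupling") %in% names(couplings)))
  if (any(abs(couplings$coupling) > 1)) stop("|coupling| must be <= 1")
  if (!all(c(couplings$parent, couplings$child) %in% names(blocks)))
    stop("couplings refer to unknown blocks")
  if (anyDuplicated(couplings$child))
    stop("couplings must form a forest (one parent per child)")
  if (any(couplings$parent == couplings$child)) stop("self-coupling")
  structure(list(blocks = blocks, weights = weights, couplings = couplings),
            class = "network_spec")
}

#' Distance ground truth for planted coupled pairs
#'
#' For every coupled block pair, the Euclidean mm distance between block
#' centroids and whether it exceeds `radius_mm` -- the range class the FCD
#' stage must recover for suprathreshold pairs.
#'
#' @param grid A [volume_grid()].
#' @param network A [network_spec()].
#' @param radius_mm Long/short range boundary (default 75).
#' @return Data frame: `parent`, `child`, `coupling`, `dist_mm`,
#'   `long_range` (TRUE iff dist > radius_mm).
#' @export
network_pair_ranges <- function(grid, network, radius_mm = 75) {
  cen <- vapply(network$blocks, function(ix) {
    vox <- arrayInd(ix, grid$shape) - 1L
    colMeans(voxel_to_mm(grid, vox))
  }, numeric(3))
  out <- network$couplings
  out$dist_mm <- vapply(seq_len(nrow(out)), function(k) {
    sqrt(sum((cen[, out$parent[k]] - cen[, out$child[k]])^2))
  }, numeric(1))
  out$long_range <- out$dist_mm > radius_mm
  out
}

#' Default planted network for a phantom
#'
#' Two coupled pairs: an anterior/posterior pair with centroid separation
#' > 75 mm (long-range) and a nearby pair well within 75 mm (short-range).
#' Block placement assumes the default desk-scale 20 x 32 x 20 grid shape or
#' larger; blocks are clipped to the mask.
#'
#' @param grid A [volume_grid()].
#' @param mask A [brain_mask()].
#' @param coupling Latent correlation for both coupled pairs (default 0.28,
#'   just below the 0.3 connectional threshold so that a group coupling
#'   delta moves pairs across it).
#' @return A [network_spec()].
#' @export
default_phantom_network <- function(grid, mask, coupling = 0.28) {
  sh <- grid$shape
  cx <- as.integer(round((sh - 1) / 2))
  blocks <- list(
    posterior = cube_block(grid, c(cx[1], 2L, cx[3]), 1L, mask),
    anterior  = cube_block(grid, c(cx[1], sh[2] - 2L, cx[3]), 1L, mask),
    left_par  = cube_block(grid, c(max(cx[1] - 7L, 1L), cx[2], cx[3]), 1L, mask),
    right_par = cube_block(grid, c(min(cx[1] + 6L, sh[1] - 2L), cx[2], cx[3]),
                           1L, mask)
  )
  if (any(lengths(blocks) == 0)) stop("phantom too small for default network")
  network_spec(blocks, weights = 1,
               couplings = data.frame(
                 parent = c("posterior", "left_par"),
                 child = c("anterior", "right_par"),
                 coupling = coupling))
}

#' Cohort specification for the synthetic BOLD generator
#'
#' Bundles the grid, mask, network and noise/effect parameters that define a
#' simulated study. The whole cohort is a pure function of `seed`.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param grid,mask Spatial frame (see [make_phantom_mask()]).
#' @param network A [network_spec()].
#' @param n_timepoints Volumes acquired per subject (>= 20); the first
#'   `n_drop` are later discarded by preprocessing.
#' @param tr_seconds Repetition time (default 2).
#' @param noise_sd Marginal SD of the AR(1) voxel noise (>= 0).
#' @param ar1 AR(1) coefficient in `[0, 1)`.
#' @param drift_amplitude SD of the shared linear drift component.
#' @param motion_amplitude Scale of simulated head motion and of its leak
#'   into the BOLD signal (0 disables).
#' @param group_effect List `(block, direction, delta)`: for patients, every
#'   coupling edge touching `block` is shifted by `+delta` ("raise") or
#'   `-delta` ("lower").
#' @param coupling_jitter_sd Per-subject SD of coupling around its
#'   specified value; gives subjects a continuous planted-FCD surrogate.
#' @param score_coupling List `(test, intercept, slope, noise_sd)`: the
#'   cognitive score is `intercept + slope * surrogate + noise`, where the
#'   surrogate is the subject's effective coupling on the target edge.
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group, grid, mask, network,
                        n_timepoints = 120L, tr_seconds = 2,
                        noise_sd = 0.3, ar1 = 0.3,
                        drift_amplitude = 0.5, motion_amplitude = 0.5,
                        group_effect = list(block = "right_par",
                                            direction = "raise", delta = 0.30),
                        coupling_jitter_sd = 0.05,
                        score_coupling = list(test = "tmt_b", intercept = 170,
                                              slope = -523.3, noise_sd = 60),
                        seed = 1L) {
  if (n_per_group < 2L) stop("need n_per_group >= 2")
  if (n_timepoints < 20L) stop("need n_timepoints >= 20")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must lie in [0, 1)")
  if (!group_effect$direction %in% c("raise", "lower"))
    stop("group_effect direction must be 'raise' or 'lower'")
  if (!group_effect$block %in% names(network$blocks))
    stop("group_effect block not in network")
  structure(list(
    n_per_group = as.integer(n_per_group), grid = grid, mask = mask,
    network = network, n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, noise_sd = noise_sd, ar1 = ar1,
    drift_amplitude = drift_amplitude, motion_amplitude = motion_amplitude,
    group_effect = group_effect, coupling_jitter_sd = coupling_jitter_sd,
    score_coupling = score_coupling, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Desk-scale default cohort
#'
#' 20 x 32 x 20 grid at 3 mm (so > 75 mm voxel separations exist inside the
#' phantom), T = 120 at TR = 2 s, 8 + 8 subjects. `scale = "full"` mirrors
#' the emulated study: 32 + 32 subjects, 240 volumes (230 after dropping 10).
#'
#' @param scale "desk" (default) or "full".
#' @param seed Master seed.
#' @param ... Overrides passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(scale = c("desk", "full"), seed = 1L, ...) {
  scale <- match.arg(scale)
  ph <- make_phantom_mask(c(20L, 32L, 20L), 3)
  net <- default_phantom_network(ph$grid, ph$mask)
  args <- list(grid = ph$grid, mask = ph$mask, network = net, seed = seed)
  if (scale == "desk") {
    args$n_per_group <- 8L; args$n_timepoints <- 120L
  } else {
    args$n_per_group <- 32L; args$n_timepoints <- 240L
  }
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# per-subject effective couplings: base + jitter (+ group delta on edges
# touching the target block, patients only); drawn from the caller's RNG
effective_couplings <- function(spec, group) {
  cp <- spec$network$couplings
  if (nrow(cp) == 0) return(cp)
  cp$coupling <- cp$coupling +
    stats::rnorm(nrow(cp), 0, spec$coupling_jitter_sd)
  if (group == "patient") {
    hit <- cp$parent == spec$group_effect$block |
      cp$child == spec$group_effect$block
    sgn <- if (spec$group_effect$direction == "raise") 1 else -1
    cp$coupling[hit] <- cp$coupling[hit] + sgn * spec$group_effect$delta
  }
  cp$coupling <- pmin(1, pmax(-1, cp$coupling))
  cp
}

# stationary AR(1) noise matrix (T x n) with marginal sd `sd`
ar1_noise <- function(nt, n, phi, sd) {
  if (sd == 0 || n == 0) return(matrix(0, nt, n))
  innov <- matrix(stats::rnorm(nt * n), nt, n)
  if (phi > 0) {
    # stationary start: x1 keeps full marginal variance, later innovations
    # are scaled so the recursion preserves it
    innov[-1, ] <- innov[-1, ] * sqrt(1 - phi^2)
    innov <- apply(innov, 2, function(x)
      stats::filter(x, phi, method = "recursive", init = 0))
  }
  innov * sd
}

#' Simulate one subject's BOLD series
#'
#' Each block voxel's series is `weight * block latent + AR(1) noise +
#' linear drift + motion-coupled component`; coupled blocks share latents
#' through the network's parent edges; background (non-block) in-mask voxels
#' carry only the nuisance components. Deterministic given
#' `(spec$seed, subject_index)`.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Positive integer.
#' @param group `"patient"` or `"control"`; the group coupling delta is
#'   applied iff `"patient"`.
#' @return List with `series` (a [bold_series()] over `spec$mask`), `motion`
#'   (T x 6 matrix, translations mm then rotations rad), `couplings` (the
#'   subject's effective coupling table) and `surrogate` (effective coupling
#'   on the group-effect edge -- the subject's planted-FCD surrogate).
#' @export
simulate_bold <- function(spec, subject_index, group = c("control", "patient")) {
  group <- match.arg(group)
  nt <- spec$n_timepoints
  set.seed((spec$seed * 10007L + subject_index * 101L) %% 2147483629L)

  cp <- effective_couplings(spec, group)
  blocks <- spec$network$blocks
  latents <- matrix(0, nt, length(blocks),
                    dimnames = list(NULL, names(blocks)))
  # roots first (couplings form a forest; parents precede children by
  # repeated sweeps)
  done <- rep(FALSE, length(blocks)); names(done) <- names(blocks)
  roots <- setdiff(names(blocks), cp$child)
  for (b in roots) { latents[, b] <- stats::rnorm(nt); done[b] <- TRUE }
  while (!all(done)) {
    for (k in seq_len(nrow(cp))) {
      ch <- cp$child[k]; pa <- cp$parent[k]
      if (!done[ch] && done[pa]) {
        c0 <- cp$coupling[k]
        latents[, ch] <- c0 * latents[, pa] +
          sqrt(1 - c0^2) * stats::rnorm(nt)
        done[ch] <- TRUE
      }
    }
  }

  n_vox <- spec$mask$n_voxels
  dat <- matrix(0, nt, n_vox)
  # map block linear grid indices to in-mask column positions
  col_of <- integer(prod(spec$grid$shape))
  col_of[spec$mask$indices] <- seq_len(n_vox)
  for (bi in seq_along(blocks)) {
    cols <- col_of[blocks[[bi]]]
    cols <- cols[cols > 0L]
    if (length(cols))
      dat[, cols] <- dat[, cols] + spec$network$weights[bi] * latents[, bi]
  }

  dat <- dat + ar1_noise(nt, n_vox, spec$ar1, spec$noise_sd)

  if (spec$drift_amplitude > 0) {
    ramp <- seq_len(nt) - (nt + 1) / 2
    ramp <- ramp / stats::sd(ramp)
    gain <- stats::runif(n_vox, 0.5, 1.5)
    dat <- dat + spec$drift_amplitude * ramp %o% gain
  }

  motion <- matrix(0, nt, 6,
                   dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                           "rot_x", "rot_y", "rot_z")))
  if (spec$motion_amplitude > 0) {
    steps <- cbind(matrix(stats::rnorm(nt * 3, 0, 0.02), nt, 3),
                   matrix(stats::rnorm(nt * 3, 0, 4e-4), nt, 3)) *
      spec$motion_amplitude
    motion <- apply(steps, 2, cumsum)
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    msum <- rowSums(scale(motion))
    msum <- msum / stats::sd(msum)
    load <- stats::runif(n_vox, 0.5, 1.5)
    dat <- dat + spec$motion_amplitude * msum %o% load
  }

  edge <- cp$parent == spec$group_effect$block |
    cp$child == spec$group_effect$block
  surrogate <- if (any(edge)) cp$coupling[which(edge)[1]] else NA_real_

  list(series = bold_series(spec$mask, dat, spec$tr_seconds),
       motion = motion, couplings = cp, surrogate = surrogate)
}

#' Simulate a full cohort to disk
#'
#' Generates `2 * n_per_group` subjects (patients then controls), optionally
#' writing one 4D NIfTI volume and one 6-column motion file per subject, and
#' returns the subject table: demographics drawn independently of group
#' (confound-free null; `confounded = TRUE` shifts patient age), mean Power
#' framewise displacement from the simulated motion, the planted-FCD
#' surrogate, and a cognitive score linearly coupled to the surrogate.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed); ignored when
#'   `volumes = FALSE`.
#' @param volumes Write per-subject volumes and motion files (default TRUE).
#' @param confounded If TRUE, patients are drawn 6 years older on average.
#' @return A validated subject table; when `volumes = TRUE` it is also
#'   written to `out_dir/subjects.tsv` and columns `volume` and
#'   `motion_file` point at the per-subject files.
#' @export
simulate_cohort <- function(spec, out_dir = NULL, volumes = TRUE,
                            confounded = FALSE) {
  n <- 2L * spec$n_per_group
  if (volumes) {
    if (is.null(out_dir)) stop("out_dir required when volumes = TRUE")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  groups <- rep(c("patient", "control"), each = spec$n_per_group)
  ids <- sprintf("sub%03d", seq_len(n))

  set.seed((spec$seed * 10007L) %% 2147483629L)
  age <- round(stats::rnorm(n, 57, 6) + if (confounded)
    ifelse(groups == "patient", 6, 0) else 0, 1)
  age <- pmin(70, pmax(45, age))
  sex <- stats::rbinom(n, 1, 0.5)
  education <- round(pmax(6, stats::rnorm(n, 10, 3)), 0)
  bmi <- round(stats::rnorm(n, 24.5, 3), 1)
  triglyceride <- round(pmax(0.3, stats::rnorm(n, 1.8, 0.8)), 2)
  hdl <- round(pmax(0.5, stats::rnorm(n, 1.2, 0.3)), 2)
  score_noise <- stats::rnorm(n, 0, spec$score_coupling$noise_sd)

  mean_fd <- numeric(n); surrogate <- numeric(n)
  vol_paths <- character(n); mot_paths <- character(n)
  for (i in seq_len(n)) {
    sim <- tryCatch(simulate_bold(spec, i, groups[i]),
                    error = function(e) stop("subject ", ids[i], ": ",
                                             conditionMessage(e)))
    surrogate[i] <- sim$surrogate
    mean_fd[i] <- power_fd(sim$motion)$mean_fd
    if (volumes) {
      vol_paths[i] <- file.path(out_dir, paste0(ids[i], "_bold.nii.gz"))
      mot_paths[i] <- file.path(out_dir, paste0(ids[i], "_motion.txt"))
      tryCatch({
        write_volume(spec$grid, series_to_array(sim$series), vol_paths[i])
        write_motion(sim$motion, mot_paths[i])
      }, error = function(e) stop("subject ", ids[i], ": ",
                                  conditionMessage(e)))
    }
  }

  score <- spec$score_coupling$intercept +
    spec$score_coupling$slope * surrogate + score_noise
  tab <- data.frame(id = ids, group = groups, age = age, sex = sex,
                    education = education, bmi = bmi,
                    triglyceride = triglyceride, hdl = hdl,
                    mean_fd = round(mean_fd, 4),
                    planted_fcd = surrogate, stringsAsFactors = FALSE)
  tab[[spec$score_coupling$test]] <- round(score, 2)
  if (volumes) {
    tab$volume <- vol_paths
    tab$motion_file <- mot_paths
  }
  tab <- validate_subject_table(tab)
  if (volumes) write_subject_table(tab, file.path(out_dir, "subjects.tsv"))
  tab
}

#' Slope giving a target score-surrogate correlation
#'
#' For `score = intercept + slope * x + e`, returns the slope for which the
#' population Pearson correlation between score and `x` equals `r`.
#' @param r Target correlation in (-1, 1).
#' @param sd_x SD of the surrogate.
#' @param sd_noise SD of the score noise.
#' @return Numeric slope.
#' @export
slope_for_target_r <- function(r, sd_x, sd_noise) {
  if (abs(r) >= 1) stop("|r| must be < 1")
  r * sd_noise / (sd_x * sqrt(1 - r^2))
}

#' Subject-level map simulation with a planted group effect
#'
#' Generates per-subject 3D maps as masked, Gaussian-smoothed white noise
#' standardised to unit in-mask SD, then adds `d` (Cohen's d, in map SD
#' units) at the effect voxels for every subject of group 1. Used for
#' inference calibration and recovery studies where the full BOLD pipeline
#' is not the object under test.
#'
#' @param mask A [brain_mask()].
#' @param n1,n2 Group sizes (group 1 receives the effect).
#' @param fwhm_mm Smoothing FWHM applied to the noise maps.
#' @param effect_indices Linear grid indices of the effect region (NULL for
#'   a pure-noise null).
#' @param d Effect size in units of the maps' in-mask SD.
#' @return List with `maps` (n_voxels x (n1 + n2) matrix, mask scan order)
#'   and `group` (factor, levels control/patient; patients first).
#' @export
simulate_group_maps <- function(mask, n1, n2, fwhm_mm = 6,
                                effect_indices = NULL, d = 0) {
  n <- n1 + n2
  maps <- matrix(0, mask$n_voxels, n)
  for (i in seq_len(n)) {
    m <- array(0, mask$grid$shape)
    m[mask$indices] <- stats::rnorm(mask$n_voxels)
    if (fwhm_mm > 0) m <- smooth_map(m, mask, fwhm_mm)
    v <- m[mask$indices]
    maps[, i] <- v / stats::sd(v)
  }
  if (!is.null(effect_indices) && d != 0) {
    rows <- match(effect_indices, mask$indices)
    if (anyNA(rows)) stop("effect indices outside mask")
    maps[rows, seq_len(n1)] <- maps[rows, seq_len(n1)] + d
  }
  list(maps = maps,
       group = factor(rep(c("patient", "control"), c(n1, n2)),
                      levels = c("control", "patient")))
}

#' Cohort scalars with a planted partial correlation
#'
#' Draws covariates and two outcomes whose population partial Pearson
#' correlation given the covariates is exactly `partial_r`; used to check
#' recovery of the brain-behaviour association stage.
#'
#' @param n Subjects.
#' @param partial_r Target population partial correlation.
#' @param n_covariates Number of shared covariates (each loading 0.5 on
#'   both outcomes).
#' @return List with `x`, `y` (length-n vectors) and `covariates`
#'   (n x n_covariates matrix).
#' @export
planted_partial_scores <- function(n, partial_r, n_covariates = 3) {
  if (abs(partial_r) >= 1) stop("|partial_r| must be < 1")
  C <- matrix(stats::rnorm(n * n_covariates), n, n_covariates)
  ex <- stats::rnorm(n); ey <- stats::rnorm(n)
  x <- drop(C %*% rep(0.5, n_covariates)) + ex
  y <- drop(C %*% rep(0.5, n_covariates)) +
    partial_r * ex + sqrt(1 - partial_r^2) * ey
  list(x = x, y = y, covariates = C)
}
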