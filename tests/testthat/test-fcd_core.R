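line_series <- function(n_vox, dat, voxel_mm = 3, tr = 2) {
  g <- tiny_grid(c(n_vox, 1, 1), voxel_mm)
  bold_series(cube_mask(g), dat, tr)
}

test_that("a single-voxel mask yields all-zero maps", {
  g <- tiny_grid(c(1, 1, 1), 3)
  s <- bold_series(cube_mask(g), matrix(rnorm(10), 10, 1), 2)
  f <- compute_fcd(s, fcd_params())
  expect_true(all(vapply(f$maps, function(m) all(m == 0), logical(1))))
})

test_that("an identical pair lands short- or long-range by its distance", {
  x <- rnorm(20)
  # centres 3 mm apart: short-range
  g <- tiny_grid(c(40, 1, 1), 3)
  flags <- array(FALSE, g$shape); flags[c(1, 2), 1, 1] <- TRUE
  s <- bold_series(brain_mask(g, flags), cbind(x, x), 2)
  f <- compute_fcd(s, fcd_params())
  expect_equal(sum(f$maps$spfcd), 2)
  expect_equal(f$maps$spfcd[1, 1, 1], 1)
  expect_equal(sum(f$maps$lpfcd) + sum(f$maps$lnfcd) + sum(f$maps$snfcd), 0)

  # same pair 90 mm apart: long-range
  flags2 <- array(FALSE, g$shape); flags2[c(1, 31), 1, 1] <- TRUE
  s2 <- bold_series(brain_mask(g, flags2), cbind(x, x), 2)
  f2 <- compute_fcd(s2, fcd_params())
  expect_equal(f2$maps$lpfcd[1, 1, 1], 1)
  expect_equal(sum(f2$maps$spfcd), 0)
})

test_that("an anticorrelated pair feeds the negative maps", {
  x <- rnorm(20)
  g <- tiny_grid(c(40, 1, 1), 3)
  flags <- array(FALSE, g$shape); flags[c(1, 31), 1, 1] <- TRUE
  s <- bold_series(brain_mask(g, flags), cbind(x, -x), 2)
  f <- compute_fcd(s, fcd_params())
  expect_equal(f$maps$lnfcd[1, 1, 1], 1)
  expect_equal(sum(f$maps$lpfcd) + sum(f$maps$spfcd), 0)
})

test_that("blocked FCD matches the brute-force oracle on a 6^3 phantom", {
  ph <- make_phantom_mask(c(6, 6, 6), 3)
  set.seed(42)
  dat <- matrix(rnorm(80 * ph$mask$n_voxels), 80, ph$mask$n_voxels)
  # add latent structure so many pairs cross the threshold
  lat <- rnorm(80)
  dat[, seq(1, ph$mask$n_voxels, by = 3)] <-
    dat[, seq(1, ph$mask$n_voxels, by = 3)] + 1.5 * lat
  s <- bold_series(ph$mask, dat, 2)

  for (mode in c("count", "weighted")) {
    p <- fcd_params(mode = mode)
    oracle <- fcd_oracle(s, p)
    for (bs in c(7L, 64L, 4096L)) {
      f <- compute_fcd(s, p, block_size = bs)
      if (mode == "count") {
        expect_identical(f$maps$lpfcd, oracle$lpfcd)
        expect_identical(f$maps$lnfcd, oracle$lnfcd)
        expect_identical(f$maps$spfcd, oracle$spfcd)
        expect_identical(f$maps$snfcd, oracle$snfcd)
      } else {
        for (nm in names(oracle))
          expect_lt(max(abs(f$maps[[nm]] - oracle[[nm]])), 1e-12)
      }
    }
  }
})

test_that("results are independent of block size", {
  ph <- make_phantom_mask(c(6, 6, 6), 3)
  set.seed(9)
  s <- bold_series(ph$mask, matrix(rnorm(40 * ph$mask$n_voxels), 40), 2)
  # counts are exactly reproducible; weighted sums accumulate in a
  # block-shape-dependent order, so agree to numerical precision
  for (mode in c("count", "weighted")) {
    p <- fcd_params(mode = mode)
    ref <- compute_fcd(s, p, block_size = 16L)
    for (bs in c(5L, 33L, 10000L)) {
      got <- compute_fcd(s, p, block_size = bs)$maps
      if (mode == "count") expect_identical(got, ref$maps)
      else for (nm in names(got))
        expect_lt(max(abs(got[[nm]] - ref$maps[[nm]])), 1e-12)
    }
  }
})

test_that("a planted hub gets its exact long- and short-range degree", {
  # hub at 0 mm, 5 partners within 75 mm, 12 beyond, all perfectly coupled
  g <- tiny_grid(c(40, 1, 1), 3)
  flags <- array(FALSE, g$shape)
  short_idx <- 2:6                     # 3..15 mm
  long_idx <- 27:38                    # 78..111 mm
  flags[c(1, short_idx, long_idx), 1, 1] <- TRUE
  m <- brain_mask(g, flags)
  x <- rnorm(30)
  s <- bold_series(m, matrix(x, 30, m$n_voxels), 2)
  f <- compute_fcd(s, fcd_params())
  expect_equal(f$maps$lpfcd[1, 1, 1], 12)
  expect_equal(f$maps$spfcd[1, 1, 1], 5)
})

test_that("conservation: distance split partitions the total degree", {
  set.seed(31)
  ph <- make_phantom_mask(c(8, 10, 8), 3)
  for (rep in 1:3) {
    dat <- matrix(rnorm(30 * ph$mask$n_voxels), 30)
    lat <- rnorm(30)
    pick <- sample(ph$mask$n_voxels, 40)
    dat[, pick] <- dat[, pick] + outer(lat, sample(c(-1.2, 1.2), 40, TRUE))
    s <- bold_series(ph$mask, dat, 2)
    split75 <- compute_fcd(s, fcd_params(radius_mm = 75))$maps
    total <- compute_fcd(s, fcd_params(radius_mm = 1e9))$maps
    expect_identical(split75$lpfcd + split75$spfcd, total$spfcd)
    expect_identical(split75$lnfcd + split75$snfcd, total$snfcd)
  }
})

test_that("endpoint counts are even (each pair contributes twice)", {
  set.seed(8)
  ph <- make_phantom_mask(c(6, 8, 6), 3)
  dat <- matrix(rnorm(25 * ph$mask$n_voxels), 25)
  f <- compute_fcd(bold_series(ph$mask, dat, 2), fcd_params())
  for (m in f$maps) expect_equal(sum(m) %% 2, 0)
})

test_that("a pair at exactly 75 mm is short-range; just beyond is long", {
  x <- rnorm(15)
  # 25 steps of exactly 3 mm = 75.0 mm
  g <- tiny_grid(c(26, 1, 1), 3)
  flags <- array(FALSE, g$shape); flags[c(1, 26), 1, 1] <- TRUE
  s <- bold_series(brain_mask(g, flags), cbind(x, x), 2)
  f <- compute_fcd(s, fcd_params())
  expect_equal(sum(f$maps$spfcd), 2)
  expect_equal(sum(f$maps$lpfcd), 0)

  # stretch the grid infinitesimally: the same pair flips to long-range
  g2 <- tiny_grid(c(26, 1, 1), 3 * (1 + 1e-12))
  s2 <- bold_series(brain_mask(g2, flags), cbind(x, x), 2)
  f2 <- compute_fcd(s2, fcd_params())
  expect_equal(sum(f2$maps$lpfcd), 2)
  expect_equal(sum(f2$maps$spfcd), 0)
})

test_that("zero-variance voxels are excluded with a warning, not an error", {
  ph <- make_phantom_mask(c(6, 6, 6), 3)
  set.seed(12)
  dat <- matrix(rnorm(20 * ph$mask$n_voxels), 20)
  dat[, 5] <- 7                        # constant voxel
  s <- bold_series(ph$mask, dat, 2)
  expect_warning(f <- compute_fcd(s, fcd_params()), "zero-variance")
  expect_equal(f$excluded, ph$mask$indices[5])
  expect_equal(f$maps$spfcd[ph$mask$indices[5]], 0)
  # remaining voxels match the oracle on the reduced data
  oracle <- suppressWarnings(fcd_oracle(s, fcd_params()))
  expect_identical(f$maps$spfcd, oracle$spfcd)
})

test_that("planted suprathreshold pairs recover their recorded range class", {
  # noiseless generator: only within-block and coupled-pair correlations
  # are suprathreshold, and their range class must match the recorded
  # centroid-distance ground truth exactly
  ph <- make_phantom_mask(c(20, 32, 20), 3)
  net <- default_phantom_network(ph$grid, ph$mask, coupling = 0.6)
  spec <- cohort_spec(n_per_group = 2L, grid = ph$grid, mask = ph$mask,
                      network = net, n_timepoints = 40L, noise_sd = 0,
                      drift_amplitude = 0, motion_amplitude = 0,
                      coupling_jitter_sd = 0,
                      group_effect = list(block = "right_par",
                                          direction = "raise", delta = 0),
                      seed = 17L)
  sim <- simulate_bold(spec, 1, "control")
  truth <- network_pair_ranges(ph$grid, net)
  # noise-free background voxels are constant and excluded (warns, by design)
  f <- suppressWarnings(compute_fcd(sim$series, fcd_params()))

  for (k in seq_len(nrow(truth))) {
    b1 <- net$blocks[[truth$parent[k]]]
    b2 <- net$blocks[[truth$child[k]]]
    n1 <- length(b1); n2 <- length(b2)
    if (truth$long_range[k]) {
      # each voxel: (own block - 1) short partners + partner block long
      expect_equal(f$maps$lpfcd[b1], rep(n2, n1))
      expect_equal(f$maps$spfcd[b1], rep(n1 - 1, n1))
    } else {
      expect_equal(f$maps$lpfcd[b1], rep(0, n1))
      expect_equal(f$maps$spfcd[b1], rep(n1 + n2 - 1, n1))
    }
  }
})

test_that("masked smoothing preserves constants and respects fwhm = 0", {
  ph <- make_phantom_mask(c(8, 8, 8), 3)
  const <- array(0, ph$grid$shape); const[ph$mask$indices] <- 4.2
  sm <- smooth_map(const, ph$mask, 4)
  expect_equal(sm[ph$mask$indices], rep(4.2, ph$mask$n_voxels),
               tolerance = 1e-10)
  expect_true(all(sm[!ph$mask$flags] == 0))

  rnd <- array(rnorm(512), ph$grid$shape)
  expect_equal(smooth_map(rnd, ph$mask, 0)[ph$mask$indices],
               rnd[ph$mask$indices])
})

test_that("smoothing a delta matches the direct-space Gaussian oracle", {
  ph <- make_phantom_mask(c(7, 7, 7), 3)
  delta <- array(0, ph$grid$shape)
  ctr <- ph$mask$indices[which.min(rowSums(mask_coords_mm(ph$mask)^2))]
  delta[ctr] <- 1
  sm <- smooth_map(delta, ph$mask, 4)
  oracle <- smooth_oracle(delta, ph$mask, 4)
  expect_lt(max(abs(sm - oracle)), 1e-6)
})

test_that("the 4 mm kernel halves at 2 mm radius", {
  g <- tiny_grid(c(21, 21, 21), 1)          # 1 mm grid to sample 2 mm
  m <- cube_mask(g)
  delta <- array(0, g$shape); delta[11, 11, 11] <- 1
  sm <- smooth_map(delta, m, 4)
  expect_equal(sm[13, 11, 11] / sm[11, 11, 11], 0.5, tolerance = 1e-6)
})

test_that("z-scoring standardises in-mask and is shift/scale invariant", {
  ph <- make_phantom_mask(c(8, 8, 8), 3)
  set.seed(6)
  mp <- array(rnorm(512, 5, 2), ph$grid$shape)
  z <- zscore_map(mp, ph$mask)
  expect_lt(abs(mean(z[ph$mask$indices])), 1e-10)
  expect_lt(abs(sd(z[ph$mask$indices]) - 1), 1e-10)
  expect_true(all(z[!ph$mask$flags] == 0))

  z2 <- zscore_map(3.7 * mp + 11, ph$mask)
  expect_lt(max(abs(z2 - z)), 1e-8)

  # two-pass oracle
  v <- mp[ph$mask$indices]
  oracle <- (v - mean(v)) / sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  expect_lt(max(abs(z[ph$mask$indices] - oracle)), 1e-12)

  expect_error(zscore_map(array(1, ph$grid$shape), ph$mask), "zero")
})

test_that("smoothing then z-scoring is the recorded normalisation path", {
  spec <- tiny_cohort_spec(seed = 13L, n_timepoints = 40L)
  sim <- simulate_bold(spec, 1, "control")
  # a small range boundary so all four maps are populated on the 8^3 phantom
  f <- compute_fcd(sim$series, fcd_params(radius_mm = 9))
  expect_equal(f$normalized, "raw")
  fs <- smooth_fcd_maps(f)
  expect_equal(fs$normalized, "smoothed")
  fz <- zscore_fcd_maps(fs)
  expect_equal(fz$normalized, "zscored")
  for (m in fz$maps) expect_lt(abs(mean(m[f$mask$indices])), 1e-10)
})
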