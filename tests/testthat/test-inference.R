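flat_mask <- function(n = 8) cube_mask(tiny_grid(c(n, n, n), 3))

test_that("identical groups give a zero t map", {
  m <- flat_mask(4)
  maps <- matrix(rnorm(m$n_voxels), m$n_voxels, 8)  # same map for everyone
  tab <- data.frame(id = paste0("s", 1:8),
                    group = rep(c("patient", "control"), each = 4))
  d <- group_design(validate_subject_table(tab))
  sm <- glm_t_map(maps, d$design, d$contrast, m)
  expect_true(all(sm$t == 0))
})

test_that("the group t equals the closed-form pooled two-sample t", {
  set.seed(10)
  m <- flat_mask(5)
  n1 <- 6; n2 <- 6
  maps <- matrix(rnorm(m$n_voxels * 12), m$n_voxels, 12)
  maps[, 1:6] <- maps[, 1:6] + 0.5
  grp <- rep(c("patient", "control"), c(6, 6))
  d <- group_design(validate_subject_table(
    data.frame(id = paste0("s", 1:12), group = grp)))
  sm <- glm_t_map(maps, d$design, d$contrast, m)
  expect_equal(sm$df, 10)

  x1 <- maps[, 1:6]; x2 <- maps[, 7:12]
  sp2 <- (rowSums((x1 - rowMeans(x1))^2) + rowSums((x2 - rowMeans(x2))^2)) /
    (n1 + n2 - 2)
  t_oracle <- (rowMeans(x1) - rowMeans(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_lt(max(abs(sm$t[m$indices] - t_oracle)), 1e-10)
})

test_that("one-sample t on near-constant +1 maps is large and positive", {
  set.seed(11)
  m <- flat_mask(4)
  maps <- matrix(1 + rnorm(m$n_voxels * 10, 0, 0.01), m$n_voxels, 10)
  sm <- glm_t_map(maps, matrix(1, 10, 1), 1, m, "one-sample")
  expect_true(all(sm$t[m$indices] > 10))
})

test_that("a constant shift of every subject's map leaves the group t unchanged", {
  set.seed(12)
  m <- flat_mask(5)
  maps <- matrix(rnorm(m$n_voxels * 14), m$n_voxels, 14)
  tab <- validate_subject_table(
    data.frame(id = paste0("s", 1:14),
               group = rep(c("patient", "control"), 7),
               age = rnorm(14, 60, 5)))
  d <- group_design(tab, covariates = "age")
  t1 <- glm_t_map(maps, d$design, d$contrast, m)$t
  t2 <- glm_t_map(maps + 3.14, d$design, d$contrast, m)$t
  expect_lt(max(abs(t1 - t2)), 1e-8)
})

test_that("GLM residuals are orthogonal to the design at every voxel", {
  set.seed(13)
  m <- flat_mask(4)
  X <- cbind(1, rep(0:1, each = 5), rnorm(10))
  maps <- matrix(rnorm(m$n_voxels * 10), m$n_voxels, 10)
  sm <- glm_t_map(maps, X, c(0, 1, 0), m)
  expect_lt(max(abs(sm$residuals %*% X)), 1e-8)
})

test_that("rank-deficient or undersized designs are rejected with names", {
  m <- flat_mask(3)
  maps <- matrix(rnorm(m$n_voxels * 6), m$n_voxels, 6)
  X <- cbind(intercept = 1, group = rep(0:1, 3), twice = 2 * rep(0:1, 3))
  expect_error(glm_t_map(maps, X, c(0, 1, 0), m), "collinear.*twice")
  expect_error(glm_t_map(maps[, 1:2], cbind(1, c(0, 1)), c(0, 1), m),
               "degrees of freedom")
})

test_that("white-noise residual smoothness estimates ~1 voxel FWHM", {
  m <- flat_mask(24)
  set.seed(14)
  est <- replicate(20, {
    res <- matrix(rnorm(m$n_voxels * 8), m$n_voxels, 8)
    estimate_smoothness(res, m)$fwhm_vox
  })
  med <- apply(est, 1, median)
  expect_true(all(med >= 0.8 & med <= 1.5))
})

test_that("smoothed-noise FWHM is recovered within 15%", {
  m <- flat_mask(24)
  set.seed(15)
  est <- replicate(20, {
    res <- vapply(1:4, function(i) {
      a <- array(rnorm(prod(m$grid$shape)), m$grid$shape)
      smooth_map(a, m, 6)[m$indices]
    }, numeric(m$n_voxels))
    mean(estimate_smoothness(res, m)$fwhm_mm)
  })
  expect_lt(abs(median(est) - 6) / 6, 0.15)
})

test_that("resel count is stable under voxel-size change at fixed mm smoothing", {
  set.seed(16)
  # estimate on an interior subcube so the check isolates the resel
  # definition from mask-boundary effects of the smoothing
  resels_at <- function(nvox, voxmm, margin_vox) {
    m <- cube_mask(tiny_grid(c(nvox, nvox, nvox), voxmm))
    inner <- array(FALSE, m$grid$shape)
    rng <- (margin_vox + 1):(nvox - margin_vox)
    inner[rng, rng, rng] <- TRUE
    mi <- brain_mask(m$grid, inner)
    est <- replicate(6, {
      res <- vapply(1:12, function(i) {
        a <- array(rnorm(prod(m$grid$shape)), m$grid$shape)
        smooth_map(a, m, 15)[mi$indices]
      }, numeric(mi$n_voxels))
      e <- estimate_smoothness(res, mi)
      # normalise to the same physical search volume (the full cube)
      e$resels * m$n_voxels / mi$n_voxels
    })
    median(est)
  }
  r3 <- resels_at(36, 3, 6)   # 108 mm cube, 3 mm voxels
  r6 <- resels_at(18, 6, 3)   # 108 mm cube, 6 mm voxels
  expect_lt(abs(r3 - r6) / r3, 0.2)
})

test_that("cluster p is strictly decreasing in extent", {
  p <- grf_cluster_p(1:500, u = 2.6, df = 14, resels = 200,
                     n_mask_voxels = 13824)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("connected components respect connectivity semantics", {
  flags <- array(FALSE, c(5, 5, 5))
  flags[2, 2, 2] <- TRUE
  expect_equal(lengths(label_clusters(flags, 26)), 1)

  # two voxels sharing only a corner
  flags[3, 3, 3] <- TRUE
  expect_equal(length(label_clusters(flags, 26)), 1)
  expect_equal(length(label_clusters(flags, 6)), 2)

  # edge-sharing pair: connected at 18 and 26, not at 6
  fl <- array(FALSE, c(4, 4, 4))
  fl[1, 1, 1] <- TRUE; fl[2, 2, 1] <- TRUE
  expect_equal(length(label_clusters(fl, 6)), 2)
  expect_equal(length(label_clusters(fl, 18)), 1)
})

test_that("labelling matches an independent flood-fill oracle", {
  set.seed(17)
  for (rep in 1:50) {
    flags <- array(runif(6^3) < 0.35, c(6, 6, 6))
    conn <- sample(c(6L, 18L, 26L), 1)
    got <- canon_components(label_clusters(flags, conn))
    want <- canon_components(floodfill_oracle(flags, conn))
    expect_identical(got, want)
  }
})

test_that("labels come out largest-first with deterministic ties", {
  flags <- array(FALSE, c(10, 4, 4))
  flags[1:2, 1, 1] <- TRUE             # size 2
  flags[5:9, 1, 1] <- TRUE             # size 5
  comps <- label_clusters(flags, 6)
  expect_equal(lengths(comps), c(5L, 2L))
})

test_that("cluster rows reproduce extent arithmetic and peak conventions", {
  # grid arranged so one voxel is exactly at mm (-3, -90, 0)
  g <- tiny_grid(c(20, 36, 20), 3, origin_mm = c(-30, -90, -30))
  m <- cube_mask(g)
  stat <- structure(list(grid = g, mask = m, t = array(0, g$shape), df = 60),
                    class = "stat_map")
  # a 36-voxel cluster on a 3 mm grid covers 972 mm^3
  vox <- which(array(seq_len(prod(g$shape)), g$shape) <= 36)
  stat$t[vox] <- -2 - runif(36)
  row <- tabulate_cluster(stat, vox)
  expect_identical(row$extent_voxels, 36L)
  expect_identical(row$extent_mm3, 972)

  # single-voxel cluster: peak is exactly its coordinate and value
  stat$t[10, 1, 11] <- -4.0559         # voxel (9, 0, 10) -> (-3, -90, 0) mm
  row2 <- tabulate_cluster(stat, which(stat$t == -4.0559))
  expect_equal(c(row2$peak_x, row2$peak_y, row2$peak_z), c(-3, -90, 0))
  expect_equal(row2$peak_t, -4.0559)

  # equal |t|: lexicographically smaller mm coordinate wins
  stat2 <- stat
  stat2$t[] <- 0
  v1 <- which(slice.index(stat2$t, 1) == 2 & slice.index(stat2$t, 2) == 1 &
                slice.index(stat2$t, 3) == 1)
  v2 <- which(slice.index(stat2$t, 1) == 7 & slice.index(stat2$t, 2) == 1 &
                slice.index(stat2$t, 3) == 1)
  stat2$t[c(v1, v2)] <- c(3.5, -3.5)
  row3 <- tabulate_cluster(stat2, c(v1, v2))
  expect_equal(row3$peak_x, voxel_to_mm(g, c(1, 0, 0))[1])

  expect_error(tabulate_cluster(stat, integer()), "empty")
})

test_that("two-sided thresholding equals the union of one-sided passes", {
  set.seed(18)
  m <- flat_mask(12)
  maps <- matrix(rnorm(m$n_voxels * 16), m$n_voxels, 16)
  blockpos <- 1:40; blockneg <- 400:440
  maps[blockpos, 1:8] <- maps[blockpos, 1:8] + 3
  maps[blockneg, 1:8] <- maps[blockneg, 1:8] - 3
  grp <- validate_subject_table(
    data.frame(id = paste0("s", 1:16),
               group = rep(c("patient", "control"), each = 8)))
  d <- group_design(grp)
  sm <- glm_t_map(maps, d$design, d$contrast, m)

  both <- grf_cluster_threshold(sm, tail = "both")
  pos <- grf_cluster_threshold(sm, tail = "positive")
  neg <- grf_cluster_threshold(sm, tail = "negative")
  expect_equal(nrow(both), nrow(pos) + nrow(neg))
  expect_setequal(
    unlist(lapply(attr(both, "members"), paste, collapse = ",")),
    c(unlist(lapply(attr(pos, "members"), paste, collapse = ",")),
      unlist(lapply(attr(neg, "members"), paste, collapse = ","))))
  # signed peaks: positive pass has positive peak t, negative negative
  expect_true(all(both$peak_t[both$tail == "positive"] > 0))
  expect_true(all(both$peak_t[both$tail == "negative"] < 0))
  # table invariant: extent_mm3 = voxels * voxel volume, exactly
  expect_identical(both$extent_mm3,
                   both$extent_voxels * m$grid$voxel_volume_mm3)
})

test_that("an all-zero t map yields an empty cluster table", {
  m <- flat_mask(6)
  stat <- structure(list(grid = m$grid, mask = m, t = array(0, m$grid$shape),
                         df = 20, fwhm_mm = rep(6, 3), resels = 50),
                    class = "stat_map")
  tab <- grf_cluster_threshold(stat)
  expect_equal(nrow(tab), 0)
})

test_that("seed FC maps reproduce per-voxel Pearson correlations", {
  ph <- make_phantom_mask(c(8, 8, 8), 3)   # ~300 voxels
  set.seed(19)
  dat <- matrix(rnorm(40 * ph$mask$n_voxels), 40)
  s <- bold_series(ph$mask, dat, 2)

  # single-voxel seed: r = 1 at the seed itself
  seed1 <- ph$mask$indices[5]
  r1 <- seed_fc_map(s, seed1)
  expect_equal(r1[seed1], 1, tolerance = 1e-12)

  # voxel orthogonalised against the seed mean: r = 0 there
  seed <- ph$mask$indices[1:10]
  sm <- rowMeans(dat[, 1:10])
  dat2 <- dat
  v <- 42
  dat2[, v] <- qr.resid(qr(cbind(1, sm)), dat[, v])
  r2 <- seed_fc_map(bold_series(ph$mask, dat2, 2), seed)
  expect_lt(abs(r2[ph$mask$indices[v]]), 1e-10)

  # full-map oracle
  oracle <- drop(cor(sm, dat))
  expect_lt(max(abs(seed_fc_map(s, seed)[ph$mask$indices] - oracle)), 1e-12)

  expect_error(seed_fc_map(s, integer()), "empty")
  expect_error(seed_fc_map(s, max(ph$mask$indices) + 1), "inside")
})

test_that("Fisher z is odd, exact at r = 0.5, and clips at |r| = 1", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  set.seed(20)
  r <- runif(100, -0.99, 0.99)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_true(all(diff(fisher_z(sort(r))) > 0))
  expect_warning(z <- fisher_z(c(0.2, 1)), "clipped")
  expect_true(is.finite(z[2]))
})
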