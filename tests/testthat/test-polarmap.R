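test_that("axis-aligned reslicing reproduces native planes", {
  set.seed(21)
  v <- array(runif(24^3), c(24, 24, 24))
  voxel <- 4
  vol <- activity_volume(v, voxel)
  # base-plane center on a voxel boundary in z and voxel centers in-plane
  center <- c((12 - 0.5) * voxel, (12 - 0.5) * voxel, 16 * voxel)
  st <- reslice_short_axis(vol, c(0, 0, 1), center, extent_mm = 5 * voxel,
                           half_size_mm = 5 * voxel,
                           center_px = c(6, 6))
  npx <- dim(st$slices)[1]
  expect_equal(npx, 11)
  for (s in 1:5) {
    z_idx <- 16 - s + 1
    expect_equal(st$slices[, , s],
                 v[(12 - 5):(12 + 5), (12 - 5):(12 + 5), z_idx],
                 tolerance = 1e-12)
  }
})

test_that("uniform volumes reslice to uniform slices", {
  vol <- activity_volume(array(2.5, c(20, 20, 20)), 4)
  st <- reslice_short_axis(vol, c(0, 0, 1), c(40, 40, 60), extent_mm = 30,
                           half_size_mm = 20, center_px = c(6, 6))
  expect_true(all(abs(st$slices - 2.5) < 1e-12))
})

test_that("radial maxima capture rings, hot pixels and uniform fields", {
  # uniform slice: every ray returns the constant
  u <- matrix(3.3, 41, 41)
  expect_equal(radial_max_profile(u, c(21, 21), 16, 15), rep(3.3, 16))
  # annulus of value 10 on background 1: all maxima are 10
  g <- expand.grid(i = 1:41, j = 1:41)
  r <- sqrt((g$i - 21)^2 + (g$j - 21)^2)
  ring <- matrix(1, 41, 41)
  ring[r >= 8 & r <= 11] <- 10
  expect_equal(radial_max_profile(ring, c(21, 21), 24, 18), rep(10, 24))
  # single hot pixel on zeros: only rays near it see it
  hot <- matrix(0, 41, 41)
  hot[21, 31] <- 5   # exactly on the theta = 0 ray at radius 10
  prof <- radial_max_profile(hot, c(21, 21), 24, 18, step_px = 0.5)
  expect_equal(prof[1], 5)
  expect_true(all(prof[7:19] == 0))    # rays at >= 90 degrees away
  expect_true(all(prof[-1] < 5))
  expect_error(radial_max_profile(hot, c(21, 21), 24, r_max_px = 0), "positive")
  expect_error(radial_max_profile(hot, c(21, 21), 4, 18), "n_rays")
})

test_that("rotating the slice by a ray step permutes the profile cyclically", {
  set.seed(31)
  sl <- matrix(runif(41 * 41), 41, 41)
  # 90 degree rotation is exact on the pixel grid; use 4 rays per quadrant
  n_rays <- 8
  prof <- radial_max_profile(sl, c(21, 21), n_rays, 17)
  rot <- t(sl)[, 41:1]   # rotate so content moves by +90 degrees of theta
  prof_rot <- radial_max_profile(rot, c(21, 21), n_rays, 17)
  shift <- n_rays / 4
  expect_equal(prof_rot,
               prof[((seq_len(n_rays) - 1 + shift) %% n_rays) + 1],
               tolerance = 1e-12)
})

test_that("polar map parcellation partitions all cells into 17 segments", {
  vol <- activity_volume(array(1.7, c(20, 20, 20)), 4)
  st <- reslice_short_axis(vol, c(0, 0, 1), c(40, 40, 64), extent_mm = 40,
                           half_size_mm = 24, center_px = c(7, 7))
  pm <- build_polar_map(st, n_rays = 60, n_rings = 30)
  expect_true(all(pm$segment_of %in% 1:17))
  st17 <- segment_stats(pm)
  expect_equal(sum(st17$n_cells), length(pm$segment_of))
  # basal and mid levels have six segments of equal size, apical four
  expect_equal(length(unique(st17$n_cells[1:6])), 1L)
  expect_equal(length(unique(st17$n_cells[7:12])), 1L)
  expect_equal(length(unique(st17$n_cells[13:16])), 1L)
  # uniform stack: constant map, all means equal, zero dispersion
  expect_equal(as.vector(pm$values), rep(1.7, length(pm$values)))
  expect_equal(st17$mean_suv, rep(1.7, 17))
  expect_equal(st17$sd_suv, rep(0, 17), tolerance = 1e-12)
})

test_that("a minimal 3-slice stack still yields the full 17-segment model", {
  vol <- activity_volume(array(1, c(20, 20, 20)), 4)
  st <- reslice_short_axis(vol, c(0, 0, 1), c(40, 40, 64), extent_mm = 12,
                           half_size_mm = 24, center_px = c(7, 7))
  expect_equal(dim(st$slices)[3], 3L)
  pm <- build_polar_map(st)
  expect_true(all(1:17 %in% pm$segment_of))
})

test_that("segment statistics match hand-computed moments", {
  pm <- structure(list(
    values = matrix(c(1, 2, 3, 0, 0, 4, 4, rep(5, 10)), 1),
    segment_of = matrix(c(1, 1, 1, 2, 2, 2, 2, 3:17), 1),
    theta = NULL, ring_frac = NULL, suv_ceiling = 4),
    class = "polar_map")
  st <- segment_stats(pm)
  expect_equal(st$mean_suv[1], 2)
  expect_equal(st$sd_suv[1], sqrt(2 / 3))        # population SD of {1,2,3}
  expect_equal(st$mean_suv[2], 2)                # {0,0,4,4}
  expect_equal(st$sd_suv[2], 2)
  sts <- segment_stats(pm, sd_type = "sample")
  expect_equal(sts$sd_suv[1], 1)                 # sample SD of {1,2,3}
  # an empty segment is an error
  pm$segment_of[1, 4:7] <- 3L
  expect_error(segment_stats(pm), "segment 2")
})

test_that("segment means track the phantom's segmental multipliers", {
  m <- rep(1, 17); m[c(2, 3, 8, 9, 14)] <- 2
  res <- pipeline_indices(clean_cardiac_spec(m))
  means <- res$stats$mean_suv
  expect_setequal(order(means, decreasing = TRUE)[1:5], c(2, 3, 8, 9, 14))
  # noiseless end-to-end recovery of mild gradients within 1 percentage point
  m2 <- rep(1, 17); m2[c(2, 3, 8, 9, 14)] <- 1.2
  res2 <- pipeline_indices(clean_cardiac_spec(m2))
  truth2 <- res2$phantom$truth$true_indices
  expect_lt(abs(res2$indices$pct_ds - truth2$pct_ds), 1)
  expect_lt(abs(res2$indices$total_cardiac_suv / truth2$total_cardiac_suv - 1),
            0.05)
})
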