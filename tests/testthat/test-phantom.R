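test_that("cylinder phantom reproduces the calibration geometry", {
  sp <- cyl_spec(grid = 128)
  ph <- make_cylinder_phantom(7.5, diameter_mm = 160, height_mm = 150,
                              spec = sp)
  vol_ml <- sum(ph$truth$mask) * sp$voxel_mm^3 / 1000
  expect_lt(abs(vol_ml / 3016 - 1), 0.02)
  # noiseless, unit count scale: every interior voxel equals the concentration
  expect_true(all(ph$volume$values[ph$truth$mask] == 7.5))
  expect_true(all(ph$volume$values[!ph$truth$mask] == 0))
})

test_that("cylinder phantom edge cases and errors", {
  sp <- cyl_spec(grid = 32)
  z <- make_cylinder_phantom(0, 60, 60, sp)
  expect_true(all(z$volume$values == 0))
  expect_error(make_cylinder_phantom(5, 1000, 60, sp), "exceeds")
})

test_that("poisson noise preserves the expected counts", {
  lam <- 40
  means <- replicate(50, {
    sp <- cyl_spec(grid = 24, fwhm = 0, count_scale = lam,
                   seed = sample.int(1e6, 1))
    ph <- make_cylinder_phantom(1, 40, 40, sp)
    mean(ph$volume$values[ph$truth$mask])
  })
  n_vox <- sum(make_cylinder_phantom(1, 40, 40, cyl_spec(24))$truth$mask)
  se <- sqrt(lam / n_vox) / sqrt(50)
  expect_lt(abs(mean(means) - lam), 3 * se)
})

test_that("cardiac phantom ground truth is well formed", {
  sp <- clean_cardiac_spec()
  ph <- make_cardiac_phantom(sp)
  expect_true(all(ph$truth$segment_labels %in% 0:17))
  expect_true(all(1:17 %in% ph$truth$segment_labels))
  expect_true(all(ph$truth$true_concentration >= 0))
  # uniform multipliers: zero heterogeneity in the truth
  expect_equal(ph$truth$true_indices$pct_ds, 0)
  expect_equal(ph$truth$true_indices$cov, 0)
  # shell thinner than a voxel is rejected
  expect_error(
    phantom_spec(myo_inner_radii = c(44, 44, 64),
                 myo_outer_radii = c(45, 45, 65)),
    "thinner")
})

test_that("septal and basal enhancement raise the true indices", {
  m_sep <- rep(1, 17); m_sep[c(2, 3, 8, 9, 14)] <- 2
  t_sep <- make_cardiac_phantom(clean_cardiac_spec(m_sep, grid = 32))$truth
  expect_gt(t_sep$true_indices$pct_ds, 0)
  expect_gt(t_sep$true_indices$summed_suv[["septal"]],
            t_sep$true_indices$summed_suv[["lateral"]])
  m_bas <- rep(1, 17); m_bas[1:12] <- 1.5
  t_bas <- make_cardiac_phantom(clean_cardiac_spec(m_bas, grid = 32))$truth
  t_uni <- make_cardiac_phantom(clean_cardiac_spec(grid = 32))$truth
  expect_gt(t_bas$true_indices$pct_ba, t_uni$true_indices$pct_ba)
})

test_that("planar projection sums columns and conserves counts", {
  v <- array(0, c(6, 7, 8))
  v[2, 3, 4] <- 5
  vol <- activity_volume(v, 2)
  pl <- project_planar(vol, axis = 2)
  expect_equal(sum(pl$values != 0), 1)
  expect_equal(pl$values[2, 4], 5)
  # uniform cube: interior pixels equal value x depth
  u <- activity_volume(array(1.5, c(5, 4, 6)), 2)
  plu <- project_planar(u, axis = "y")
  expect_true(all(plu$values == 1.5 * 4))
  # conservation holds for arbitrary volumes and axes
  w <- activity_volume(array(runif(5 * 4 * 6), c(5, 4, 6)), 2)
  for (ax in 1:3)
    expect_equal(sum(project_planar(w, ax)$values), sum(w$values))
  expect_error(project_planar(w, 4), "axis")
})

test_that("synthetic echo columns hit their target correlations", {
  base <- data.frame(idx = stats::rnorm(200, 50, 10))
  # |r| = 1 is a noiseless affine map
  e1 <- synth_echo(base, data.frame(index = "idx", echo = "e",
                                    r = 1, noise_sd = 0), seed = 1)
  expect_equal(stats::cor(e1$idx, e1$e), 1)
  # r = 0.78, n = 200: sample correlation within 0.1 across 100 seeds
  devs <- vapply(1:100, function(s) {
    set.seed(s + 5000)
    d <- data.frame(idx = stats::rnorm(200, 50, 10))
    d <- synth_echo(d, data.frame(index = "idx", echo = "e",
                                  r = 0.78, noise_sd = 2), seed = s)
    stats::cor(d$idx, d$e) - 0.78
  }, numeric(1))
  expect_lt(max(abs(devs)), 0.1)
  # negative targets give negative sample correlations almost surely (n = 20)
  neg <- vapply(1:100, function(s) {
    set.seed(s + 9000)
    d <- data.frame(idx = stats::rnorm(20, 50, 10))
    d <- synth_echo(d, data.frame(index = "idx", echo = "e",
                                  r = -0.625, noise_sd = 3), seed = s)
    stats::cor(d$idx, d$e) < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
  expect_error(synth_echo(base, data.frame(index = "nope", echo = "e",
                                           r = 0.5, noise_sd = 1)),
               "unknown index")
})
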