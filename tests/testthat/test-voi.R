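test_that("voi_mean over uniform and constructed fields", {
  u <- suv_volume(array(1.76, c(32, 32, 32)), 4, 1, 1)
  sph <- ellipsoid_voi(c(64, 64, 64), c(30, 30, 30))
  cyl <- cylinder_voi(c(64, 64, 64), diameter_mm = 40, height_mm = 19.5)
  expect_equal(voi_mean(u, sph), 1.76)
  expect_equal(voi_mean(u, cyl), 1.76)
  # half the VOI voxels 2.0, half 0.0 -> mean 1.0 (split along a symmetry plane)
  v <- array(0, c(32, 32, 32)); v[1:16, , ] <- 2
  half <- suv_volume(v, 4, 1, 1)
  expect_equal(voi_mean(half, ellipsoid_voi(c(64, 64, 64), c(24, 24, 24))), 1)
  # VOI entirely outside the grid errors
  expect_error(voi_mean(u, ellipsoid_voi(c(1000, 1000, 1000), c(5, 5, 5))),
               "no voxel")
})

test_that("voi_mean is invariant under joint whole-voxel translation", {
  set.seed(11)
  v <- array(runif(20^3), c(20, 20, 20))
  vol <- suv_volume(v, 4, 1, 1)
  voi <- ellipsoid_voi(c(30, 40, 36), c(14, 10, 12))
  m0 <- voi_mean(vol, voi)
  shift <- c(2L, -1L, 3L)   # voxels
  vs <- array(0, dim(v))
  vs[3:20, 1:19, 4:20] <- v[1:18, 2:20, 1:17]
  voln <- suv_volume(vs, 4, 1, 1)
  voi2 <- ellipsoid_voi(voi$center_mm + shift * 4, voi$radii_mm)
  expect_equal(voi_mean(voln, voi2), m0)
})

test_that("differentiation metrics combine heart and aortic VOIs", {
  # three aortic cylinders with means 1.0 / 1.2 / 0.8 average to 1.0
  v <- array(0, c(40, 40, 40))
  vol_mm <- 4
  centers <- list(c(80, 80, 40), c(80, 80, 80), c(80, 80, 120))
  vals <- c(1.0, 1.2, 0.8)
  ao <- list()
  for (i in 1:3) {
    ao[[i]] <- cylinder_voi(centers[[i]], diameter_mm = 24, height_mm = 19.5)
  }
  suv <- suv_volume(array(1, c(40, 40, 40)), vol_mm, 1, 1)
  for (i in 1:3) {
    m <- voi_mask(suv, ao[[i]])
    suv$values[m] <- vals[i]
  }
  heart <- ellipsoid_voi(c(40, 40, 80), c(16, 16, 16))
  suv$values[voi_mask(suv, heart)] <- 1.85
  dm <- differentiation_metrics(suv, heart, ao)
  expect_equal(dm$suv_ao, 1.0)
  expect_equal(dm$suv_h, 1.85)
  expect_equal(dm$rsuv, 1.85)
  expect_error(differentiation_metrics(suv, heart, ao[1:2]), "three")
})

test_that("a phantom can be tuned to the reported amyloid heart/aorta ratio", {
  # heart-VOI mean is affine in the myocardial level; solve for rSUV = 1.85
  mk <- function(level) {
    sp <- phantom_spec(grid_shape = rep(48L, 3), myo_base_level = level,
                       psf_fwhm_mm = 0, count_scale = 1, seed = NULL)
    ph <- make_cardiac_phantom(sp)
    suv <- suv_volume(ph$volume$values, sp$voxel_mm, 1, 1)
    vois <- phantom_vois(sp)
    differentiation_metrics(suv, vois$heart, vois$aorta)
  }
  d0 <- mk(1e-9); d1 <- mk(1)
  a <- d0$suv_h; b <- d1$suv_h - a
  target_level <- (1.85 * d1$suv_ao - a) / b
  dm <- mk(target_level)
  expect_equal(dm$rsuv, 1.85, tolerance = 1e-6)
})

test_that("rsuv and hcl are invariant to global rescaling", {
  sp <- phantom_spec(grid_shape = rep(48L, 3), psf_fwhm_mm = 0,
                     count_scale = 1, seed = NULL)
  ph <- make_cardiac_phantom(sp)
  vois <- phantom_vois(sp)
  planar <- project_planar(ph$volume, 2)
  hc <- c(sp$lv_center_mm[1], sp$lv_center_mm[3])
  s1 <- suv_volume(ph$volume$values, sp$voxel_mm, 1, 1)
  s2 <- suv_volume(ph$volume$values * 4.2, sp$voxel_mm, 1, 1)
  d1 <- differentiation_metrics(s1, vois$heart, vois$aorta, planar,
                                heart_center_mm = hc)
  pl2 <- planar_image(planar$values * 7, planar$pixel_mm)
  d2 <- differentiation_metrics(s2, vois$heart, vois$aorta, pl2,
                                heart_center_mm = hc)
  expect_equal(d1$rsuv, d2$rsuv)
  expect_equal(d1$hcl, d2$hcl)
})

test_that("classification uses >= cutoff with ties positive", {
  mkres <- function(rsuv, hcl = NA) structure(
    list(suv_h = 1, suv_ao = 1, rsuv = rsuv, hcl = hcl),
    class = "differentiation_result")
  expect_true(classify_uptake(mkres(1.85), 1.2)$attr_positive_rsuv)
  expect_false(classify_uptake(mkres(0.75), 1.2)$attr_positive_rsuv)
  expect_true(classify_uptake(mkres(2, hcl = 1.3))$attr_positive_hcl)
  expect_true(is.na(classify_uptake(mkres(2))$attr_positive_hcl))
  expect_error(classify_uptake(mkres(1), rsuv_cutoff = -1), "positive")
})
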