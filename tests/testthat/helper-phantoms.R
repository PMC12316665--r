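# small, fast phantom specs shared across tests

# cylinder acquisitions: geometry fields are irrelevant
cyl_spec <- function(grid = 64, voxel = 3.9, fwhm = 0, count_scale = 1,
                     seed = NULL) {
  phantom_spec(grid_shape = rep(grid, 3L), voxel_mm = voxel,
               psf_fwhm_mm = fwhm, count_scale = count_scale, seed = seed)
}

# noiseless, blur-free cardiac phantom with myocardium only (background 0),
# for exact parameter-recovery checks
clean_cardiac_spec <- function(mult = rep(1, 17), grid = 64, level = 2, ...) {
  phantom_spec(grid_shape = rep(grid, 3L), segment_multipliers = mult,
               myo_base_level = level, blood_pool_level = 0, lung_level = 0,
               aorta_level = 0, psf_fwhm_mm = 0, count_scale = 1,
               seed = NULL, ...)
}

# phantom -> SUV -> polar map -> indices with identity calibration
pipeline_indices <- function(spec, ...) {
  ph <- make_cardiac_phantom(spec)
  cal <- cross_calibration(1 / spec$count_scale)
  suv <- counts_to_suv(ph$volume, cal, dose_bq = 1, weight_g = 1)
  ci <- cardiac_indices(suv, spec$lv_axis, spec$lv_center_mm,
                        extent_mm = spec$myo_outer_radii[3], ...)
  c(list(phantom = ph, suv = suv), ci)
}

# independently coded tie-corrected Kruskal-Wallis H (oracle for tests)
kw_brute_force <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  Rj <- vapply(split(r, rep(seq_along(groups), lengths(groups))), sum, 1)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# printed reference correlations of the regional-SUV table
reference_correlations <- data.frame(
  subset = rep(c("all", "wt", "v"), each = 3),
  index = rep(c("cov", "pct_ds", "pct_ba"), 3),
  r = c(-0.254, -0.295, -0.100,
        -0.385, -0.728, 0.226,
        -0.740, -0.039, -0.486)
)
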