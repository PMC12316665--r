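#' Digital phantom specification
#'
#' Parameters of the seeded digital phantoms used to validate the SUV
#' quantification pipeline. The cardiac phantom places a truncated
#' ellipsoidal left-ventricular shell (closed apex, open base) over a
#' blood-pool cavity, two low-uptake lung boxes and a descending-aorta
#' cylinder, assigns each shell voxel its AHA segment geometrically, scales
#' segmental uptake by `segment_multipliers`, blurs with a Gaussian point
#' spread function and (when a seed is given) draws Poisson counts.
#'
#' Defaults mirror a typical acquisition: a 128-cube matrix at 3.9 mm
#' isotropic voxels and an 8 mm FWHM reconstruction filter. Activity levels
#' are in SUV-like units relative to a blood pool of 1.0; the default
#' myocardial level of 3.2 yields whole-heart VOI means near the values
#' reported for amyloid-positive patients.
#'
#' @param grid_shape integer length-3 vector of voxel counts per axis.
#' @param voxel_mm isotropic voxel size (mm).
#' @param myo_outer_radii,myo_inner_radii length-3 ellipsoid semi-axes (mm)
#'   of the LV shell: two in-plane radii then the long-axis radius.
#' @param lv_center_mm LV base-plane center in world mm (default: grid
#'   center shifted 50 mm toward -x so a contralateral lung field exists).
#' @param lv_axis unit long-axis direction, pointing apex to base.
#' @param anterior anterior reference direction (angular origin).
#' @param segment_multipliers 17 nonnegative uptake scale factors.
#' @param myo_base_level,blood_pool_level,lung_level,aorta_level activity
#'   concentrations (Bq/mL in arbitrary SUV-like units).
#' @param psf_fwhm_mm Gaussian blur FWHM (mm); 0 disables blurring.
#' @param count_scale expected counts per voxel per unit concentration.
#' @param aorta_diameter_mm diameter of the descending-aorta cylinder.
#' @param seed RNG seed; `NULL` returns noiseless expected counts.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 128L),
                         voxel_mm = 3.9,
                         myo_outer_radii = c(45, 45, 65),
                         myo_inner_radii = c(30, 30, 50),
                         lv_center_mm = NULL,
                         lv_axis = c(0, 0, 1),
                         anterior = c(0, 1, 0),
                         segment_multipliers = rep(1, 17),
                         myo_base_level = 3.2,
                         blood_pool_level = 1.0,
                         lung_level = 0.25,
                         aorta_level = 1.0,
                         psf_fwhm_mm = 8,
                         count_scale = 100,
                         aorta_diameter_mm = 20,
                         seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(lv_center_mm))
    lv_center_mm <- grid_shape * voxel_mm / 2 + c(-50, 0, 0)
  spec <- structure(list(
    grid_shape = grid_shape, voxel_mm = voxel_mm,
    myo_outer_radii = myo_outer_radii, myo_inner_radii = myo_inner_radii,
    lv_center_mm = lv_center_mm, lv_axis = lv_axis, anterior = anterior,
    segment_multipliers = segment_multipliers,
    myo_base_level = myo_base_level, blood_pool_level = blood_pool_level,
    lung_level = lung_level, aorta_level = aorta_level,
    psf_fwhm_mm = psf_fwhm_mm, count_scale = count_scale,
    aorta_diameter_mm = aorta_diameter_mm, seed = seed
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 8L))
      stop("grid_shape must be three values >= 8")
    if (voxel_mm <= 0) stop("voxel_mm must be positive")
    if (any(myo_outer_radii <= 0) || any(myo_inner_radii <= 0))
      stop("ellipsoid radii must be positive")
    if (any(myo_inner_radii >= myo_outer_radii))
      stop("inner radii must be strictly smaller than outer radii")
    if (length(segment_multipliers) != 17L)
      stop("segment_multipliers must have length 17")
    if (any(segment_multipliers < 0))
      stop("segment_multipliers must be nonnegative")
    if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
    if (count_scale <= 0) stop("count_scale must be positive")
    if (min(myo_outer_radii - myo_inner_radii) < voxel_mm)
      stop("myocardial shell is thinner than one voxel")
  })
  invisible(spec)
}

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

# world coordinates of all voxel centers, as three arrays
coord_arrays <- function(grid_shape, voxel_mm) {
  cx <- voxel_centers(grid_shape[1], voxel_mm)
  cy <- voxel_centers(grid_shape[2], voxel_mm)
  cz <- voxel_centers(grid_shape[3], voxel_mm)
  list(
    x = array(cx, grid_shape),
    y = array(rep(cy, each = grid_shape[1]), grid_shape),
    z = array(rep(cz, each = grid_shape[1] * grid_shape[2]), grid_shape)
  )
}

poisson_counts <- function(concentration, spec) {
  lambda <- concentration * spec$count_scale
  if (is.null(spec$seed)) return(lambda)
  cnt <- with_seed(spec$seed,
                   stats::rpois(length(lambda), pmax(lambda, 0)))
  array(as.numeric(cnt), dim = dim(lambda))
}

#' Uniform cylinder calibration phantom
#'
#' Simulates a SPECT acquisition of a uniform cylinder of known activity
#' concentration (the cross-calibration measurement). The cylinder axis is
#' the grid z axis, centered in the field of view. The concentration map is
#' blurred with the spec's PSF and converted to counts with expectation
#' `concentration * count_scale`; Poisson noise is drawn when the spec
#' carries a seed.
#'
#' @param concentration activity concentration inside the cylinder (Bq/mL).
#' @param diameter_mm,height_mm cylinder inner dimensions (mm); defaults are
#'   the 16 cm x 15 cm (3016 mL) calibration cylinder.
#' @param spec a [phantom_spec] (geometry fields other than grid/psf/count
#'   scale/seed are ignored).
#' @return List with `volume` (an [activity_volume] of counts) and
#'   `truth` (list: `true_concentration` array, `mask` of interior voxels).
#' @export
make_cylinder_phantom <- function(concentration,
                                  diameter_mm = 160, height_mm = 150,
                                  spec = phantom_spec()) {
  if (concentration < 0) stop("concentration must be >= 0")
  fov <- spec$grid_shape * spec$voxel_mm
  if (diameter_mm > fov[1] || diameter_mm > fov[2] || height_mm > fov[3])
    stop("cylinder exceeds grid bounds")
  co <- coord_arrays(spec$grid_shape, spec$voxel_mm)
  ctr <- fov / 2
  mask <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 <= (diameter_mm / 2)^2 &
          abs(co$z - ctr[3]) <= height_mm / 2
  conc <- array(0, spec$grid_shape)
  conc[mask] <- concentration
  blurred <- gaussian_blur3(conc, spec$psf_fwhm_mm, spec$voxel_mm)
  counts <- poisson_counts(blurred, spec)
  list(
    volume = activity_volume(counts, spec$voxel_mm),
    truth = list(true_concentration = conc, mask = mask)
  )
}

# descending aorta: vertical cylinder at the posterior midline
aorta_position <- function(spec) {
  fov <- spec$grid_shape * spec$voxel_mm
  c(fov[1] / 2, spec$lv_center_mm[2] - spec$myo_outer_radii[2] - 25)
}

# per-voxel geometry of the cardiac phantom: segment labels and tissue masks
cardiac_geometry <- function(spec) {
  co <- coord_arrays(spec$grid_shape, spec$voxel_mm)
  B <- lv_frame(spec$lv_axis, spec$anterior)
  dx <- co$x - spec$lv_center_mm[1]
  dy <- co$y - spec$lv_center_mm[2]
  dz <- co$z - spec$lv_center_mm[3]
  q1 <- dx * B["e1", 1] + dy * B["e1", 2] + dz * B["e1", 3]
  q2 <- dx * B["e2", 1] + dy * B["e2", 2] + dz * B["e2", 3]
  u  <- dx * B["a", 1] + dy * B["a", 2] + dz * B["a", 3]
  ro <- spec$myo_outer_radii; ri <- spec$myo_inner_radii
  Eo <- (q1 / ro[1])^2 + (q2 / ro[2])^2 + (u / ro[3])^2
  Ei <- (q1 / ri[1])^2 + (q2 / ri[2])^2 + (u / ri[3])^2
  heart <- u <= 0 & Eo <= 1
  shell <- heart & Ei > 1
  cavity <- heart & Ei <= 1

  # parcellation rule (shared with the polar map): the deepest 10% of the
  # LV length is the apex cap; the remaining 90% splits into equal thirds
  labels <- array(0L, spec$grid_shape)
  idx <- which(shell)
  theta <- atan2(-q1[idx], q2[idx]) %% (2 * pi)
  frac <- -u[idx] / ro[3]                # 0 at base, 1 at apex tip
  seg <- integer(length(idx))
  apex <- frac > 0.9
  seg[apex] <- 17L
  t3 <- pmin(floor(frac[!apex] / 0.3), 2)
  th <- theta[!apex]
  s <- integer(sum(!apex))
  s[t3 == 0] <- aha_sector6(th[t3 == 0])
  s[t3 == 1] <- aha_sector6(th[t3 == 1]) + 6L
  s[t3 == 2] <- aha_sector4(th[t3 == 2])
  seg[!apex] <- s
  labels[idx] <- seg

  fov <- spec$grid_shape * spec$voxel_mm
  aorta_xy <- aorta_position(spec)
  aorta <- !heart &
    (co$x - aorta_xy[1])^2 + (co$y - aorta_xy[2])^2 <=
      (spec$aorta_diameter_mm / 2)^2 &
    co$z > 0.1 * fov[3] & co$z < 0.9 * fov[3]

  lungs <- !heart & !aorta &
    abs(co$y - spec$lv_center_mm[2]) <= 60 &
    abs(co$z - spec$lv_center_mm[3]) <= 80 &
    (co$x >= spec$lv_center_mm[1] + spec$myo_outer_radii[1] + 10 &
       co$x <= fov[1] - 8 |
     co$x <= spec$lv_center_mm[1] - spec$myo_outer_radii[1] - 10 &
       co$x >= 8)

  list(shell = shell, cavity = cavity, aorta = aorta, lungs = lungs,
       labels = labels, aorta_xy = aorta_xy, frame = B)
}

#' Cardiac uptake phantom
#'
#' Builds a 3D activity map with a left-ventricular shell whose segmental
#' uptake is `myo_base_level * segment_multipliers[s]`, a blood-pool cavity,
#' a descending-aorta cylinder, and two lung fields, then blurs with the
#' PSF and converts to counts (Poisson-sampled when the spec has a seed).
#' Ground truth carries the noiseless pre-blur concentration map, per-voxel
#' AHA segment labels and the regional index set implied by the segment
#' multipliers.
#'
#' @param spec a [phantom_spec].
#' @return List with `volume` ([activity_volume] of counts) and `truth`
#'   (class `ground_truth`): `true_concentration`, `segment_labels`,
#'   `true_indices`, and LV geometry metadata.
#' @export
make_cardiac_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  geo <- cardiac_geometry(spec)
  conc <- array(0, spec$grid_shape)
  conc[geo$lungs] <- spec$lung_level
  conc[geo$aorta] <- spec$aorta_level
  conc[geo$cavity] <- spec$blood_pool_level
  sh <- which(geo$shell)
  conc[sh] <- spec$myo_base_level * spec$segment_multipliers[geo$labels[sh]]
  blurred <- gaussian_blur3(conc, spec$psf_fwhm_mm, spec$voxel_mm)
  counts <- poisson_counts(blurred, spec)

  seg_means <- spec$myo_base_level * spec$segment_multipliers
  true_indices <- if (all(seg_means > 0)) {
    compute_indices(segment_stats_from_moments(seg_means, rep(0, 17)))
  } else NULL

  truth <- structure(list(
    true_concentration = conc,
    segment_labels = geo$labels,
    true_indices = true_indices,
    lv_center_mm = spec$lv_center_mm, lv_axis = spec$lv_axis,
    anterior = spec$anterior,
    myo_outer_radii = spec$myo_outer_radii,
    myo_inner_radii = spec$myo_inner_radii,
    aorta_xy_mm = geo$aorta_xy
  ), class = "ground_truth")

  list(volume = activity_volume(counts, spec$voxel_mm), truth = truth)
}

#' Standard VOIs for a cardiac phantom
#'
#' The whole-heart ellipsoid VOI encloses the truncated LV shell with an
#' 8 mm margin; the three aortic cylinder VOIs sit on the phantom's
#' descending aorta at the upper, middle and lower thirds of the axial
#' field of view, each 19.5 mm tall.
#'
#' @param spec a [phantom_spec].
#' @return List with `heart` (an [ellipsoid_voi]) and `aorta` (list of
#'   three [cylinder_voi]).
#' @export
phantom_vois <- function(spec) {
  B <- lv_frame(spec$lv_axis, spec$anterior)
  ro <- spec$myo_outer_radii
  center <- spec$lv_center_mm - B["a", ] * ro[3] / 2
  heart <- ellipsoid_voi(center,
                         radii_mm = c(ro[1] + 8, ro[2] + 8, ro[3] / 2 + 8),
                         orientation = t(B))
  fov <- spec$grid_shape * spec$voxel_mm
  aorta_xy <- aorta_position(spec)
  aorta <- lapply(c(0.3, 0.5, 0.7), function(f)
    cylinder_voi(center_mm = c(aorta_xy, f * fov[3]),
                 axis = c(0, 0, 1),
                 diameter_mm = 0.8 * spec$aorta_diameter_mm,
                 height_mm = 19.5))
  list(heart = heart, aorta = aorta)
}

#' Project a volume to a planar image
#'
#' Column sums of voxel values along one grid axis, emulating a planar
#' (static) acquisition. Projection along axis 2 of the default phantom
#' geometry gives the anterior view.
#'
#' @param volume an [activity_volume].
#' @param axis projection axis: 1, 2 or 3 (or `"x"`, `"y"`, `"z"`).
#' @return A [planar_image]; total counts are conserved exactly.
#' @export
project_planar <- function(volume, axis = 2L) {
  if (is.character(axis)) axis <- match(tolower(axis), c("x", "y", "z"))
  if (is.na(axis) || !axis %in% 1:3) stop("axis must be one of 1:3 or x/y/z")
  keep <- setdiff(1:3, axis)
  m <- apply(volume$values, keep, sum)
  planar_image(m, volume$voxel_mm)
}

#' Attach synthetic echocardiographic columns to a cohort table
#'
#' Each echo column is generated as an affine transform of a named imaging
#' index plus Gaussian noise with the requested standard deviation, with the
#' slope chosen so the expected Pearson correlation equals the target. With
#' `|r| = 1` the transform is noiseless regardless of `noise_sd`.
#'
#' @param cohort data.frame of per-subject indices.
#' @param targets data.frame with columns `index` (existing column name),
#'   `echo` (new column name), `r` (target correlation, in `[-1, 1]`) and
#'   `noise_sd` (> 0 unless `|r| = 1`).
#' @param seed RNG seed.
#' @return `cohort` with the new echo columns appended.
#' @export
synth_echo <- function(cohort, targets, seed = 1L) {
  stopifnot(is.data.frame(cohort), is.data.frame(targets))
  need <- c("index", "echo", "r", "noise_sd")
  if (!all(need %in% names(targets)))
    stop("targets must have columns index, echo, r, noise_sd")
  if (any(abs(targets$r) > 1)) stop("|r| must be <= 1")
  miss <- setdiff(targets$index, names(cohort))
  if (length(miss)) stop("unknown index column(s): ",
                         paste(miss, collapse = ", "))
  with_seed(seed, {
    for (i in seq_len(nrow(targets))) {
      x <- cohort[[targets$index[i]]]
      r <- targets$r[i]; s <- targets$noise_sd[i]
      if (abs(r) == 1) {
        y <- sign(r) * x
      } else {
        if (s <= 0) stop("noise_sd must be > 0 when |r| < 1")
        sx <- stats::sd(x)
        if (sx == 0) stop("index '", targets$index[i], "' has zero variance")
        b <- sign(r) * s * abs(r) / (sx * sqrt(1 - r^2))
        y <- b * (x - mean(x)) + stats::rnorm(length(x), 0, s)
      }
      cohort[[targets$echo[i]]] <- y
    }
  })
  cohort
}

#' Simulate a differentiation cohort of cardiac phantoms
#'
#' Generates amyloid-like and control phantoms and computes their
#' differentiation metrics. Amyloid-like subjects draw a voxel-level
#' myocardium-to-blood concentration ratio uniformly from `attr_ratio`;
#' controls draw from `control_ratio` (default 0.6-1.0). The default
#' amyloid range of 3.2-5.5 is what a whole-heart VOI containing the blood
#' pool requires to land on the reported amyloid-positive group statistics
#' (heart-to-aorta SUV ratio 1.85 +- 0.47, whole-heart mean SUV about 1.8
#' over a unit blood pool): roughly 40% of that VOI is myocardium, so the
#' VOI mean dilutes the voxel-level ratio by more than half. Blood-pool
#' level varies mildly between subjects.
#'
#' @param n_attr,n_control group sizes.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param grid_shape,voxel_mm phantom grid (smaller grids run faster).
#' @param attr_ratio,control_ratio length-2 ranges of the
#'   myocardium-to-blood ratio.
#' @param psf_fwhm_mm,count_scale forwarded to [phantom_spec()].
#' @return data.frame: `id`, `group` (`"ATTR"`/`"control"`), `ratio_true`,
#'   `suv_h`, `suv_ao`, `rsuv`, `hcl`.
#' @export
simulate_differentiation_cohort <- function(n_attr = 20, n_control = 20,
                                            seed = 1L,
                                            grid_shape = c(64L, 64L, 64L),
                                            voxel_mm = 3.9,
                                            attr_ratio = c(3.2, 5.5),
                                            control_ratio = c(0.6, 1.0),
                                            psf_fwhm_mm = 8,
                                            count_scale = 100) {
  n <- n_attr + n_control
  pars <- with_seed(seed, {
    data.frame(
      sub_seed = sample.int(.Machine$integer.max - 1L, n),
      blood = pmax(stats::rnorm(n, 1.0, 0.08), 0.5),
      ratio = c(stats::runif(n_attr, attr_ratio[1], attr_ratio[2]),
                stats::runif(n_control, control_ratio[1], control_ratio[2]))
    )
  })
  group <- rep(c("ATTR", "control"), c(n_attr, n_control))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phantom_spec(
      grid_shape = grid_shape, voxel_mm = voxel_mm,
      myo_base_level = pars$blood[i] * pars$ratio[i],
      blood_pool_level = pars$blood[i],
      aorta_level = pars$blood[i],
      lung_level = 0.25 * pars$blood[i],
      psf_fwhm_mm = psf_fwhm_mm, count_scale = count_scale,
      seed = pars$sub_seed[i]
    )
    ph <- make_cardiac_phantom(spec)
    cal <- cross_calibration(1 / spec$count_scale, source = "simulated")
    suv <- counts_to_suv(ph$volume, cal, dose_bq = 1, weight_g = 1)
    vois <- phantom_vois(spec)
    planar <- project_planar(ph$volume, axis = 2L)
    dm <- differentiation_metrics(
      suv, vois$heart, vois$aorta, planar = planar,
      heart_center_mm = c(spec$lv_center_mm[1], spec$lv_center_mm[3]),
      roi_radius_mm = 30
    )
    out[[i]] <- data.frame(id = i, group = group[i],
                           ratio_true = pars$ratio[i],
                           suv_h = dm$suv_h, suv_ao = dm$suv_ao,
                           rsuv = dm$rsuv, hcl = dm$hcl)
  }
  do.call(rbind, out)
}

#' Serialize phantom ground truth
#'
#' Writes the segment-label volume as integer NIfTI and the true regional
#' indices as JSON alongside.
#'
#' @param truth a `ground_truth` object from [make_cardiac_phantom()].
#' @param dir output directory (created if needed).
#' @param voxel_mm voxel size of the label volume.
#' @return Invisibly, the two file paths.
#' @export
write_ground_truth <- function(truth, dir, voxel_mm) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- file.path(dir, "segment_labels.nii.gz")
  write_volume(activity_volume(truth$segment_labels + 0, voxel_mm,
                               units = "label"), lab)
  js <- file.path(dir, "true_indices.json")
  jsonlite::write_json(unclass(truth$true_indices), js,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(labels = lab, indices = js))
}
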