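#' Ellipsoidal volume of interest
#'
#' An ellipsoid in world coordinates (mm). A voxel belongs to the VOI when
#' its center falls inside the ellipsoid (no partial-volume weighting).
#'
#' @param center_mm ellipsoid center (length-3, mm).
#' @param radii_mm semi-axes (length-3, mm).
#' @param orientation 3x3 rotation matrix whose columns are the ellipsoid
#'   axis directions in world coordinates (default: grid-aligned).
#' @return Object of class `ellipsoid_voi`.
#' @export
ellipsoid_voi <- function(center_mm, radii_mm, orientation = diag(3)) {
  if (any(radii_mm <= 0)) stop("radii must be positive")
  stopifnot(length(center_mm) == 3L, length(radii_mm) == 3L,
            all(dim(orientation) == c(3L, 3L)))
  structure(list(center_mm = as.numeric(center_mm),
                 radii_mm = as.numeric(radii_mm),
                 orientation = orientation),
            class = c("ellipsoid_voi", "voi"))
}

#' Cylindrical volume of interest
#'
#' Used for the aortic blood-pool reference; the default height of 19.5 mm
#' corresponds to five 3.9 mm pixels. The diameter is adjusted per subject
#' to the width of the aorta.
#'
#' @param center_mm cylinder center (length-3, mm).
#' @param axis cylinder axis direction (normalized internally).
#' @param diameter_mm,height_mm cylinder dimensions (mm).
#' @return Object of class `cylinder_voi`.
#' @export
cylinder_voi <- function(center_mm, axis = c(0, 0, 1),
                         diameter_mm, height_mm = 19.5) {
  if (diameter_mm <= 0 || height_mm <= 0)
    stop("diameter and height must be positive")
  structure(list(center_mm = as.numeric(center_mm),
                 axis = axis / sqrt(sum(axis^2)),
                 diameter_mm = as.numeric(diameter_mm),
                 height_mm = as.numeric(height_mm)),
            class = c("cylinder_voi", "voi"))
}

#' Logical mask of voxels inside a VOI
#'
#' @param volume an [activity_volume].
#' @param voi an [ellipsoid_voi] or [cylinder_voi].
#' @return Logical array with the volume's dimensions.
#' @export
voi_mask <- function(volume, voi) {
  co <- coord_arrays(dim(volume$values), volume$voxel_mm)
  dx <- co$x - voi$center_mm[1]
  dy <- co$y - voi$center_mm[2]
  dz <- co$z - voi$center_mm[3]
  if (inherits(voi, "ellipsoid_voi")) {
    R <- voi$orientation
    l1 <- dx * R[1, 1] + dy * R[2, 1] + dz * R[3, 1]
    l2 <- dx * R[1, 2] + dy * R[2, 2] + dz * R[3, 2]
    l3 <- dx * R[1, 3] + dy * R[2, 3] + dz * R[3, 3]
    (l1 / voi$radii_mm[1])^2 + (l2 / voi$radii_mm[2])^2 +
      (l3 / voi$radii_mm[3])^2 <= 1
  } else if (inherits(voi, "cylinder_voi")) {
    a <- voi$axis
    u <- dx * a[1] + dy * a[2] + dz * a[3]
    r2 <- dx^2 + dy^2 + dz^2 - u^2
    abs(u) <= voi$height_mm / 2 & r2 <= (voi$diameter_mm / 2)^2
  } else stop("unsupported VOI type")
}

#' Mean value inside a VOI
#'
#' Arithmetic mean over voxels whose centers fall inside the VOI.
#'
#' @param volume an [activity_volume] or [suv_volume].
#' @param voi an [ellipsoid_voi] or [cylinder_voi].
#' @return Mean voxel value.
#' @export
voi_mean <- function(volume, voi) {
  m <- voi_mask(volume, voi)
  if (!any(m)) stop("VOI contains no voxel centers")
  mean(volume$values[m])
}

#' Planar heart-to-contralateral-lung ratio
#'
#' Mean counts inside an equal-area circular heart ROI divided by the mean
#' inside a lung ROI of the same size. Unless given explicitly, the lung
#' ROI is the heart ROI mirrored across the image vertical midline at the
#' same height.
#'
#' @param planar a [planar_image] (anterior view; axes are left-right and
#'   inferior-superior).
#' @param heart_center_mm ROI center, length-2 (mm).
#' @param roi_radius_mm ROI radius (mm).
#' @param lung_center_mm optional explicit lung ROI center; default mirrors
#'   the heart ROI.
#' @return List with `hcl`, `heart_mean`, `lung_mean`.
#' @export
hcl_ratio <- function(planar, heart_center_mm, roi_radius_mm = 30,
                      lung_center_mm = NULL) {
  stopifnot(inherits(planar, "planar_image"))
  d <- dim(planar$values)
  width_mm <- d[1] * planar$pixel_mm
  if (is.null(lung_center_mm))
    lung_center_mm <- c(width_mm - heart_center_mm[1], heart_center_mm[2])
  px <- voxel_centers(d[1], planar$pixel_mm)
  pz <- voxel_centers(d[2], planar$pixel_mm)
  X <- matrix(px, d[1], d[2])
  Z <- matrix(pz, d[1], d[2], byrow = TRUE)
  roi_mean <- function(c2) {
    m <- (X - c2[1])^2 + (Z - c2[2])^2 <= roi_radius_mm^2
    if (!any(m)) stop("ROI contains no pixels")
    mean(planar$values[m])
  }
  hm <- roi_mean(heart_center_mm)
  lm <- roi_mean(lung_center_mm)
  if (lm <= 0) stop("lung ROI mean is not positive")
  list(hcl = hm / lm, heart_mean = hm, lung_mean = lm)
}

#' Heart/aorta differentiation metrics
#'
#' Computes the whole-heart mean SUV, the aortic blood-pool reference (the
#' unweighted mean of three cylindrical VOI means along the descending
#' aorta), their ratio, and optionally the planar heart-to-contralateral
#' lung ratio.
#'
#' @param volume a [suv_volume].
#' @param heart an [ellipsoid_voi] enclosing the entire heart.
#' @param aorta list of exactly three [cylinder_voi].
#' @param planar optional [planar_image] for the H/CL ratio.
#' @param heart_center_mm,roi_radius_mm,lung_center_mm planar ROI geometry,
#'   see [hcl_ratio()].
#' @return Object of class `differentiation_result`: `suv_h`, `suv_ao`,
#'   `aorta_means`, `rsuv`, `hcl` (NA when no planar image given).
#' @export
differentiation_metrics <- function(volume, heart, aorta, planar = NULL,
                                    heart_center_mm = NULL,
                                    roi_radius_mm = 30,
                                    lung_center_mm = NULL) {
  if (!is.list(aorta) || length(aorta) != 3L)
    stop("exactly three aortic VOIs are required")
  suv_h <- voi_mean(volume, heart)
  ao <- vapply(aorta, function(v) voi_mean(volume, v), numeric(1))
  suv_ao <- mean(ao)
  if (suv_ao <= 0) stop("aortic mean SUV is not positive; ratio undefined")
  hcl <- NA_real_
  if (!is.null(planar)) {
    if (is.null(heart_center_mm))
      stop("heart_center_mm is required when a planar image is given")
    hcl <- hcl_ratio(planar, heart_center_mm, roi_radius_mm,
                     lung_center_mm)$hcl
  }
  structure(list(suv_h = suv_h, suv_ao = suv_ao, aorta_means = ao,
                 rsuv = suv_h / suv_ao, hcl = hcl),
            class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat(sprintf("<differentiation_result> SUV_H %.3f | SUV_Ao %.3f | rSUV_H/Ao %.3f | H/CL %s\n",
              x$suv_h, x$suv_ao, x$rsuv,
              if (is.na(x$hcl)) "-" else sprintf("%.3f", x$hcl)))
  invisible(x)
}

#' Classify a subject from its differentiation metrics
#'
#' A metric at or above its cutoff is called positive (ties positive). The
#' ratio cutoff defaults to 1.2, the midpoint of the 1.1-1.3 range over
#' which perfect separation of amyloid-positive subjects was observed; the
#' planar cutoff defaults to the conventional 1.3.
#'
#' @param result a `differentiation_result`.
#' @param rsuv_cutoff cutoff on the heart-to-aorta SUV ratio.
#' @param hcl_cutoff cutoff on the planar H/CL ratio.
#' @return List of logicals `attr_positive_rsuv`, `attr_positive_hcl`
#'   (NA when H/CL was not computed).
#' @export
classify_uptake <- function(result, rsuv_cutoff = 1.2, hcl_cutoff = 1.3) {
  if (rsuv_cutoff <= 0 || hcl_cutoff <= 0) stop("cutoffs must be positive")
  list(attr_positive_rsuv = result$rsuv >= rsuv_cutoff,
       attr_positive_hcl = if (is.na(result$hcl)) NA else
         result$hcl >= hcl_cutoff)
}
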