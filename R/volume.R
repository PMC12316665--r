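#' 3D activity volume
#'
#' Minimal container for a reconstructed SPECT volume: a 3D numeric array of
#' voxel values (counts/voxel or Bq/mL) plus an isotropic voxel size in mm.
#' World coordinates place voxel centers at `(i - 0.5) * voxel_mm` along each
#' axis, so the grid spans `[0, dim * voxel_mm]`.
#'
#' @param values 3D numeric array.
#' @param voxel_mm isotropic voxel edge length in mm.
#' @param units free-text unit label (e.g. "count/voxel", "Bq/mL").
#' @return An object of class `activity_volume`.
#' @export
activity_volume <- function(values, voxel_mm, units = "count/voxel") {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 1L || !is.finite(voxel_mm) || voxel_mm <= 0)
    stop("voxel_mm must be a single positive number")
  structure(list(values = values, voxel_mm = voxel_mm, units = units),
            class = "activity_volume")
}

#' @export
print.activity_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels @ %.3g mm [%s]\n",
              class(x)[1L], d[1], d[2], d[3], x$voxel_mm, x$units))
  cat(sprintf("  range [%.4g, %.4g], total %.6g\n",
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

#' SUV volume
#'
#' An [activity_volume] whose values are dimensionless body-weight
#' standardized uptake values, carrying the injected dose and body weight
#' used in the conversion.
#'
#' @param values 3D numeric array of SUVs (all values must be >= 0).
#' @param voxel_mm isotropic voxel size (mm).
#' @param dose_bq injected dose in Bq.
#' @param weight_g body weight in g.
#' @return Object of class `suv_volume` (also `activity_volume`).
#' @export
suv_volume <- function(values, voxel_mm, dose_bq, weight_g) {
  if (!is.numeric(dose_bq) || dose_bq <= 0) stop("dose_bq must be positive")
  if (!is.numeric(weight_g) || weight_g <= 0) stop("weight_g must be positive")
  if (any(values < 0)) stop("SUV values must be nonnegative")
  v <- activity_volume(values, voxel_mm, units = "SUV")
  v$dose_bq <- as.numeric(dose_bq)
  v$weight_g <- as.numeric(weight_g)
  class(v) <- c("suv_volume", class(v))
  v
}

#' Planar image
#'
#' 2D projection image (e.g. an anterior planar acquisition) with its pixel
#' size. Pixel centers sit at `(i - 0.5) * pixel_mm`.
#'
#' @param values 2D numeric matrix.
#' @param pixel_mm isotropic pixel size in mm.
#' @return Object of class `planar_image`.
#' @export
planar_image <- function(values, pixel_mm) {
  stopifnot(is.matrix(values))
  if (pixel_mm <= 0) stop("pixel_mm must be positive")
  structure(list(values = values, pixel_mm = as.numeric(pixel_mm)),
            class = "planar_image")
}

# world-coordinate voxel center positions along each axis
voxel_centers <- function(n, voxel_mm) (seq_len(n) - 0.5) * voxel_mm

grid_center_mm <- function(vol) dim(vol$values) * vol$voxel_mm / 2

#' Separable Gaussian blur of a 3D array
#'
#' Applies an isotropic Gaussian filter (stated as full width at half
#' maximum in mm) along each axis in turn. Kernels are truncated at 3 sigma
#' and renormalized at the array edges, so constant regions are preserved
#' exactly away from boundaries.
#'
#' @param values 3D numeric array.
#' @param fwhm_mm full width at half maximum of the Gaussian, in mm.
#'   `0` disables filtering.
#' @param voxel_mm voxel size in mm.
#' @return Blurred array of the same dimensions.
#' @export
gaussian_blur3 <- function(values, fwhm_mm, voxel_mm) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(values)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm   # in voxels
  for (axis in 1:3) values <- blur_axis(values, sigma, axis)
  values
}

blur_axis <- function(v, sigma_vox, axis) {
  d <- dim(v)
  n <- d[axis]
  hw <- max(1L, ceiling(3 * sigma_vox))
  x <- (-hw):hw
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + x
    ok <- idx >= 1L & idx <= n
    K[i, idx[ok]] <- k[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  perm <- c(axis, setdiff(1:3, axis))
  vp <- aperm(v, perm)
  m <- K %*% matrix(vp, nrow = n)
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

#' Trilinear interpolation in a 3D array
#'
#' Samples `values` at continuous 1-based voxel-index coordinates. Points
#' outside the grid return 0.
#'
#' @param values 3D numeric array.
#' @param pts n x 3 matrix of continuous voxel-index coordinates.
#' @return Numeric vector of n interpolated values.
#' @export
interp3 <- function(values, pts) {
  d <- dim(values)
  out <- numeric(nrow(pts))
  inside <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
            pts[, 2] >= 1 & pts[, 2] <= d[2] &
            pts[, 3] >= 1 & pts[, 3] <= d[3]
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  i0 <- pmin(pmax(floor(p), 1), matrix(rep(d - 1L, each = nrow(p)), ncol = 3))
  f <- p - i0
  acc <- numeric(nrow(p))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
    acc <- acc + w * values[idx]
  }
  out[inside] <- acc
  out
}

#' Bilinear interpolation in a matrix
#'
#' @param values numeric matrix.
#' @param pts n x 2 matrix of continuous 1-based index coordinates.
#' @return Numeric vector; points outside the matrix give 0.
#' @export
interp2 <- function(values, pts) {
  d <- dim(values)
  out <- numeric(nrow(pts))
  inside <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
            pts[, 2] >= 1 & pts[, 2] <= d[2]
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  i0 <- pmin(pmax(floor(p), 1), matrix(rep(d - 1L, each = nrow(p)), ncol = 2))
  f <- p - i0
  acc <- (1 - f[, 1]) * (1 - f[, 2]) * values[cbind(i0[, 1], i0[, 2])] +
         f[, 1] * (1 - f[, 2]) * values[cbind(i0[, 1] + 1L, i0[, 2])] +
         (1 - f[, 1]) * f[, 2] * values[cbind(i0[, 1], i0[, 2] + 1L)] +
         f[, 1] * f[, 2] * values[cbind(i0[, 1] + 1L, i0[, 2] + 1L)]
  out[inside] <- acc
  out
}

#' Write a volume to NIfTI
#'
#' Voxel spacing is stored in the header pixdim. Planar images are written
#' with a singleton third axis.
#'
#' @param vol an [activity_volume], [suv_volume] or [planar_image].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "planar_image")) {
    arr <- array(vol$values, dim = c(dim(vol$values), 1L))
    sp <- vol$pixel_mm
  } else {
    arr <- vol$values
    sp <- vol$voxel_mm
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(sp, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file. A singleton third axis is collapsed to a
#'   [planar_image].
#' @param units unit label to attach.
#' @return An [activity_volume] or [planar_image].
#' @export
read_volume <- function(path, units = "count/voxel") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1]
  arr <- as.array(img)
  if (length(dim(arr)) == 2L)   # singleton axis collapsed on read
    return(planar_image(arr, sp))
  if (length(dim(arr)) == 3L && dim(arr)[3] == 1L)
    return(planar_image(arr[, , 1L], sp))
  activity_volume(arr, sp, units = units)
}
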