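#' Cross-calibration factor
#'
#' Conversion factor from reconstructed SPECT counts per voxel to activity
#' concentration (Bq/mL), measured on a uniform cylinder phantom of known
#' concentration.
#'
#' @param ccf positive finite factor, (Bq/mL) per (count/voxel).
#' @param source free-text description of the calibration acquisition.
#' @return Object of class `cross_calibration`.
#' @export
cross_calibration <- function(ccf, source = "") {
  if (!is.numeric(ccf) || length(ccf) != 1L || !is.finite(ccf) || ccf <= 0)
    stop("ccf must be a single positive finite number")
  structure(list(ccf = as.numeric(ccf), source = source),
            class = "cross_calibration")
}

#' @export
print.cross_calibration <- function(x, ...) {
  cat(sprintf("<cross_calibration> ccf = %.6g (Bq/mL)/(count/voxel)", x$ccf))
  if (nzchar(x$source)) cat(" [", x$source, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Estimate the cross-calibration factor from a cylinder acquisition
#'
#' `ccf = true_concentration / mean(counts)` over an interior mask. By
#' default the supplied cylinder mask is eroded by one PSF FWHM so the
#' partial-volume rim near the cylinder wall does not bias the mean.
#'
#' @param counts [activity_volume] of reconstructed counts.
#' @param true_concentration known concentration in the cylinder (Bq/mL).
#' @param mask logical array marking cylinder-interior voxels.
#' @param erode_mm rim to strip from the mask before averaging (mm);
#'   0 disables erosion.
#' @return A [cross_calibration].
#' @export
estimate_ccf <- function(counts, true_concentration, mask, erode_mm = 8) {
  stopifnot(inherits(counts, "activity_volume"), is.logical(mask))
  if (true_concentration <= 0) stop("true_concentration must be positive")
  if (!any(mask)) stop("mask is empty")
  if (erode_mm > 0) {
    k <- round(erode_mm / counts$voxel_mm)
    for (i in seq_len(k)) mask <- erode6(mask)
    if (!any(mask)) stop("mask empty after erosion; reduce erode_mm")
  }
  m <- mean(counts$values[mask])
  if (m <= 0) stop("mean masked count is not positive; cannot calibrate")
  cross_calibration(true_concentration / m,
                    source = sprintf("cylinder, %d voxels, erode %g mm",
                                     sum(mask), erode_mm))
}

# one round of 6-neighbour binary erosion
erode6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, axis, by) {
    r <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by > 0) { idx_dst[[axis]] <- 2:n;       idx_src[[axis]] <- 1:(n - 1) }
    else        { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    r[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    r
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) out <- out & shift(mask, axis, by)
  out
}

#' Convert a count volume to body-weight SUV
#'
#' `SUV = counts * ccf / (dose_bq / weight_g)`. Negative reconstructed
#' counts are clamped to zero (a message reports how many voxels were
#' affected).
#'
#' @param counts [activity_volume] of counts/voxel.
#' @param cal a [cross_calibration].
#' @param dose_bq injected dose (Bq).
#' @param weight_g body weight (g).
#' @return A [suv_volume].
#' @export
counts_to_suv <- function(counts, cal, dose_bq, weight_g) {
  stopifnot(inherits(counts, "activity_volume"),
            inherits(cal, "cross_calibration"))
  if (dose_bq <= 0) stop("dose_bq must be positive")
  if (weight_g <= 0) stop("weight_g must be positive")
  v <- counts$values
  nneg <- sum(v < 0)
  if (nneg > 0) {
    message(nneg, " negative count voxel(s) clamped to zero")
    v[v < 0] <- 0
  }
  suv_volume(v * cal$ccf / (dose_bq / weight_g),
             counts$voxel_mm, dose_bq, weight_g)
}

#' Protocol dose for a given body weight
#'
#' The administered activity is standardized to a 60 kg body weight:
#' `555 * weight_kg / 60` MBq, capped at 555 MBq.
#'
#' @param weight_kg body weight in kg.
#' @return Dose in MBq.
#' @export
pyp_dose_mbq <- function(weight_kg) {
  if (any(weight_kg <= 0)) stop("weight_kg must be positive")
  pmin(555, 555 * weight_kg / 60)
}

#' Write / read a cross-calibration as JSON
#' @param cal a [cross_calibration].
#' @param path JSON file path.
#' @return `write_ccf` returns `path` invisibly; `read_ccf` a
#'   [cross_calibration].
#' @export
write_ccf <- function(cal, path) {
  jsonlite::write_json(list(ccf = cal$ccf,
                            units = "(Bq/mL)/(count/voxel)",
                            source = cal$source),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ccf
#' @export
read_ccf <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cross_calibration(x$ccf, source = x$source %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
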