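#' Reslice a volume into left-ventricular short-axis slices
#'
#' Extracts planes orthogonal to the LV long axis by trilinear
#' interpolation, ordered base to apex, at the volume's native in-plane
#' resolution. The first slice sits half a spacing below the base plane
#' (the plane through `lv_center_mm`), the last near `extent_mm` toward the
#' apex.
#'
#' @param volume an [activity_volume] or [suv_volume].
#' @param lv_axis LV long-axis direction, apex to base (normalized
#'   internally).
#' @param lv_center_mm center of the LV base plane, world mm.
#' @param extent_mm distance from base plane to apex covered by the stack.
#' @param anterior anterior reference direction for the in-plane axes.
#' @param slice_spacing_mm distance between slices (default: voxel size).
#' @param half_size_mm in-plane half-extent of each slice (default 100 mm).
#' @param center_px optional n x 2 matrix of per-slice LV centers in slice
#'   pixel coordinates; by default the centroid of pixels above 50% of the
#'   slice maximum.
#' @return Object of class `short_axis_stack`: `slices` (3D array, third
#'   axis base to apex), `pixel_mm`, `slice_spacing_mm`, `center_px`.
#' @export
reslice_short_axis <- function(volume, lv_axis, lv_center_mm, extent_mm,
                               anterior = c(0, 1, 0),
                               slice_spacing_mm = NULL,
                               half_size_mm = 100,
                               center_px = NULL) {
  stopifnot(inherits(volume, "activity_volume"))
  if (extent_mm <= 0) stop("extent_mm must be positive")
  fov <- dim(volume$values) * volume$voxel_mm
  if (extent_mm > max(fov)) stop("extent_mm exceeds the grid")
  if (is.null(slice_spacing_mm)) slice_spacing_mm <- volume$voxel_mm
  B <- lv_frame(lv_axis, anterior)
  n_slices <- max(3L, as.integer(round(extent_mm / slice_spacing_mm)))
  npx <- 2L * as.integer(ceiling(half_size_mm / volume$voxel_mm)) + 1L
  q <- (seq_len(npx) - (npx + 1) / 2) * volume$voxel_mm
  Q1 <- matrix(q, npx, npx)
  Q2 <- matrix(q, npx, npx, byrow = TRUE)
  slices <- array(0, c(npx, npx, n_slices))
  for (s in seq_len(n_slices)) {
    u <- -(s - 0.5) * slice_spacing_mm
    px <- lv_center_mm[1] + Q1 * B["e1", 1] + Q2 * B["e2", 1] + u * B["a", 1]
    py <- lv_center_mm[2] + Q1 * B["e1", 2] + Q2 * B["e2", 2] + u * B["a", 2]
    pz <- lv_center_mm[3] + Q1 * B["e1", 3] + Q2 * B["e2", 3] + u * B["a", 3]
    pts <- cbind(as.vector(px), as.vector(py), as.vector(pz)) /
      volume$voxel_mm + 0.5
    slices[, , s] <- interp3(volume$values, pts)
  }
  if (is.null(center_px)) {
    center_px <- t(vapply(seq_len(n_slices), function(s) {
      sl <- slices[, , s]
      thr <- 0.5 * max(sl)
      if (thr <= 0) return(c((npx + 1) / 2, (npx + 1) / 2))
      w <- which(sl >= thr, arr.ind = TRUE)
      colMeans(w)
    }, numeric(2)))
  } else {
    center_px <- matrix(center_px, ncol = 2)
    if (nrow(center_px) == 1L)
      center_px <- center_px[rep(1L, n_slices), , drop = FALSE]
  }
  if (any(center_px[, 1] < 1 | center_px[, 1] > npx |
          center_px[, 2] < 1 | center_px[, 2] > npx))
    stop("slice centers fall outside the slice bounds")
  structure(list(slices = slices, pixel_mm = volume$voxel_mm,
                 slice_spacing_mm = slice_spacing_mm,
                 center_px = center_px),
            class = "short_axis_stack")
}

#' Maximum value along radial rays of a slice
#'
#' For each of `n_rays` equally spaced angles, samples the slice by
#' bilinear interpolation at sub-pixel steps from the center out to
#' `r_max_px` and returns the maximum along each ray. Angle 0 points to the
#' anterior wall (+column direction) and angles increase toward the septum.
#'
#' @param slice numeric matrix (one short-axis slice).
#' @param center_px length-2 center in 1-based pixel coordinates.
#' @param n_rays number of rays (>= 8).
#' @param r_max_px maximal sampling radius in pixels.
#' @param step_px radial sampling step in pixels (default 0.5).
#' @return Numeric vector of `n_rays` maxima.
#' @export
radial_max_profile <- function(slice, center_px, n_rays = 60,
                               r_max_px, step_px = 0.5) {
  if (n_rays < 8) stop("n_rays must be >= 8")
  if (r_max_px <= 0) stop("r_max_px must be positive")
  d <- dim(slice)
  if (center_px[1] < 1 || center_px[1] > d[1] ||
      center_px[2] < 1 || center_px[2] > d[2])
    stop("center must lie inside the slice")
  theta <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  r <- seq(0, r_max_px, by = step_px)
  # direction: theta = 0 -> +e2 (anterior), theta = pi/2 -> -e1 (septal)
  d1 <- -sin(theta); d2 <- cos(theta)
  p1 <- center_px[1] + outer(r, d1)
  p2 <- center_px[2] + outer(r, d2)
  vals <- interp2(slice, cbind(as.vector(p1), as.vector(p2)))
  dim(vals) <- c(length(r), n_rays)
  apply(vals, 2, max)
}

#' Build a polar map from a short-axis stack
#'
#' Radial-maximum profiles of the slices are arranged concentrically with
#' the base at the outer edge and the apex at the center. The map uses a
#' fixed number of rings; each ring takes the profile of the nearest slice,
#' so coarse stacks are oversampled rather than dropped. Rings are
#' parcellated into the AHA 17-segment model: the innermost
#' `ceil(apex_cap_frac * n_rings)` rings form the apex cap (segment 17) at
#' all angles, and the remaining rings split into equal basal (six
#' 60-degree sectors, segments 1-6), mid (7-12) and apical (four 90-degree
#' sectors, 13-16) levels. With the default 30 rings and 10% cap the level
#' boundaries fall at 30%, 60% and 90% of the stack extent, matching the
#' geometric rule used for phantom ground-truth labels.
#'
#' @param stack a [short_axis_stack].
#' @param n_rays number of rays per ring.
#' @param n_rings number of polar-map rings (default 30).
#' @param r_max_px maximal sampling radius (default: largest radius fully
#'   inside the slice).
#' @param step_px radial sampling step in pixels.
#' @param apex_cap_frac fraction of innermost rings assigned to the apex
#'   cap.
#' @param suv_ceiling display ceiling stored for rendering (default 4.0).
#' @return Object of class `polar_map`: `values` (n_rings x n_rays, ring 1
#'   = base), `segment_of` (same shape, values 1-17), `theta`, `ring_frac`,
#'   `suv_ceiling`.
#' @export
build_polar_map <- function(stack, n_rays = 60, n_rings = 30,
                            r_max_px = NULL, step_px = 0.5,
                            apex_cap_frac = 0.1, suv_ceiling = 4.0) {
  stopifnot(inherits(stack, "short_axis_stack"))
  n_slices <- dim(stack$slices)[3]
  d <- dim(stack$slices)[1:2]
  if (is.null(r_max_px))
    r_max_px <- max(1, min(
      min(stack$center_px[, 1] - 1), min(d[1] - stack$center_px[, 1]),
      min(stack$center_px[, 2] - 1), min(d[2] - stack$center_px[, 2])))
  profiles <- t(vapply(seq_len(n_slices), function(s)
    radial_max_profile(stack$slices[, , s], stack$center_px[s, ],
                       n_rays = n_rays, r_max_px = r_max_px,
                       step_px = step_px),
    numeric(n_rays)))
  ring_frac <- (seq_len(n_rings) - 0.5) / n_rings
  ring_slice <- pmin(pmax(ceiling(ring_frac * n_slices), 1L), n_slices)
  values <- profiles[ring_slice, , drop = FALSE]

  theta <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  n_cap <- ceiling(apex_cap_frac * n_rings)
  # thirds over the non-cap rings: 1 basal, 2 mid, 3 apical
  third <- pmin(ceiling(3 * seq_len(n_rings) / (n_rings - n_cap)), 3L)
  segment_of <- matrix(0L, n_rings, n_rays)
  for (i in seq_len(n_rings)) {
    segment_of[i, ] <-
      if (i > n_rings - n_cap) rep(17L, n_rays)
      else if (third[i] == 1L) aha_sector6(theta)
      else if (third[i] == 2L) aha_sector6(theta) + 6L
      else aha_sector4(theta)
  }
  if (!all(1:17 %in% segment_of))
    stop("parcellation leaves empty segments; increase n_rings/n_rays")
  structure(list(values = values, segment_of = segment_of, theta = theta,
                 ring_frac = ring_frac, suv_ceiling = suv_ceiling),
            class = "polar_map")
}

#' Per-segment statistics of a polar map
#'
#' Mean and standard deviation of the polar-map cell values in each of the
#' 17 AHA segments. The SD denominator defaults to the population form
#' (divide by n), treating the segment's cells as the complete set of
#' samples whose dispersion is described; `"sample"` switches to n - 1.
#'
#' @param pm a [polar_map].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Object of class `segment_stats`: data.frame with columns
#'   `segment`, `mean_suv`, `sd_suv`, `n_cells`.
#' @export
segment_stats <- function(pm, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(pm, "polar_map"))
  seg <- as.vector(pm$segment_of)
  val <- as.vector(pm$values)
  out <- data.frame(segment = 1:17, mean_suv = NA_real_,
                    sd_suv = NA_real_, n_cells = 0L)
  for (s in 1:17) {
    v <- val[seg == s]
    if (!length(v)) stop("segment ", s, " has no polar-map cells")
    n <- length(v)
    m <- mean(v)
    ss <- sum((v - m)^2)
    out$mean_suv[s] <- m
    out$sd_suv[s] <- if (sd_type == "population") sqrt(ss / n)
                     else if (n > 1) sqrt(ss / (n - 1)) else 0
    out$n_cells[s] <- n
  }
  class(out) <- c("segment_stats", "data.frame")
  out
}

#' Construct segment statistics from known moments
#'
#' Utility for building a [segment_stats] table directly from per-segment
#' means and SDs (e.g. phantom ground truth).
#'
#' @param means,sds numeric length-17 vectors.
#' @param n_cells cell counts (default 1).
#' @return A `segment_stats` data.frame.
#' @export
segment_stats_from_moments <- function(means, sds, n_cells = rep(1L, 17)) {
  stopifnot(length(means) == 17L, length(sds) == 17L)
  if (any(sds < 0)) stop("sds must be >= 0")
  out <- data.frame(segment = 1:17, mean_suv = as.numeric(means),
                    sd_suv = as.numeric(sds), n_cells = as.integer(n_cells))
  class(out) <- c("segment_stats", "data.frame")
  out
}

#' Render a polar map
#'
#' Bullseye display with the base at the outer edge, apex at the center,
#' anterior wall up and the septum to the left-hand side of the viewer.
#' Values are clipped at `ceiling` (default: the map's stored display
#' ceiling, conventionally 4.0 SUV).
#'
#' @param pm a [polar_map].
#' @param ceiling display ceiling.
#' @param palette color palette function name passed to
#'   [grDevices::hcl.colors()].
#' @param draw_segments outline the 17 AHA segments.
#' @return Invisibly, `pm`.
#' @export
plot_polar_map <- function(pm, ceiling = pm$suv_ceiling,
                           palette = "Inferno", draw_segments = TRUE) {
  n_rings <- nrow(pm$values); n_rays <- ncol(pm$values)
  cols <- grDevices::hcl.colors(256, palette)
  graphics::plot.new()
  graphics::plot.window(c(-1.05, 1.05), c(-1.05, 1.05), asp = 1)
  dth <- 2 * pi / n_rays
  for (i in seq_len(n_rings)) {
    r_out <- (n_rings - i + 1) / n_rings
    r_in <- (n_rings - i) / n_rings
    for (k in seq_len(n_rays)) {
      th <- seq(pm$theta[k] - dth / 2, pm$theta[k] + dth / 2, length.out = 8)
      # display: anterior (theta 0) up, septum to the left
      xx <- c(r_out * -sin(th), rev(r_in * -sin(th)))
      yy <- c(r_out * cos(th), rev(r_in * cos(th)))
      v <- min(max(pm$values[i, k] / ceiling, 0), 1)
      graphics::polygon(xx, yy, border = NA,
                        col = cols[1 + floor(v * 255)])
    }
  }
  if (draw_segments) {
    for (r in c(1, 2 / 3, 1 / 3)) graphics::symbols(
      0, 0, circles = r, inches = FALSE, add = TRUE, fg = "grey40")
  }
  invisible(pm)
}
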