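#' Summed SUV of a myocardial region
#'
#' Sum of the per-segment mean SUVs over the segments of a named region
#' (see [aha_region_segments()] for the two grouping schemes).
#'
#' @param stats a [segment_stats] table.
#' @param region region name: `"anterior"`, `"septal"`, `"inferior"`,
#'   `"lateral"`, `"apical"` (segment 17 only), `"basal"` (1-12),
#'   `"apical5"` (13-17) or `"all"`.
#' @return The summed SUV.
#' @export
summed_region <- function(stats, region) {
  segs <- aha_region_segments(region)
  sum(stats$mean_suv[stats$segment %in% segs])
}

#' Total coefficient of variation
#'
#' Sum over the 17 segments of the segmental COV, where segmental COV is
#' the within-segment SD divided by the segment mean, times 100. Higher
#' values indicate more heterogeneous uptake.
#'
#' @param stats a [segment_stats] table.
#' @return COV (percent units, summed over 17 segments).
#' @export
total_cov <- function(stats) {
  zero <- which(stats$mean_suv <= 0)
  if (length(zero))
    stop("segment(s) with nonpositive mean SUV: ",
         paste(stats$segment[zero], collapse = ", "))
  sum(stats$sd_suv / stats$mean_suv) * 100
}

#' Septal-lateral difference score (%DS)
#'
#' `(Summed SUV_septal - Summed SUV_lateral) / Summed SUV_all * 100`.
#' Positive values indicate septal-predominant uptake.
#'
#' @param stats a [segment_stats] table.
#' @return %DS.
#' @export
percent_ds <- function(stats) {
  total <- summed_region(stats, "all")
  if (total <= 0) stop("total summed SUV is not positive")
  (summed_region(stats, "septal") - summed_region(stats, "lateral")) /
    total * 100
}

#' Base-to-apex variability (%BA)
#'
#' `(Summed SUV_basal - Summed SUV_apical) / Summed SUV_all * 100` with
#' basal = segments 1-12 and apical = segments 13-17. Note that a perfectly
#' uniform ventricle gives %BA = (12 - 5)/17 * 100 = 41.18 because the two
#' regions contain unequal numbers of segments.
#'
#' @param stats a [segment_stats] table.
#' @return %BA.
#' @export
percent_ba <- function(stats) {
  total <- summed_region(stats, "all")
  if (total <= 0) stop("total summed SUV is not positive")
  (summed_region(stats, "basal") - summed_region(stats, "apical5")) /
    total * 100
}

#' Regional index set
#'
#' Computes all regional uptake indices from per-segment statistics: the
#' summed SUVs of the named regions, total cardiac SUV (sum of all 17
#' segment means), COV, %DS and %BA. The two partitions are exact by
#' construction: basal + apical5 = total and
#' anterior + septal + inferior + lateral + apical = total.
#'
#' @param stats a [segment_stats] table.
#' @return Object of class `regional_index_set`: `summed_suv` (named
#'   vector), `total_cardiac_suv`, `cov`, `pct_ds`, `pct_ba`.
#' @export
compute_indices <- function(stats) {
  stopifnot(inherits(stats, "segment_stats") || is.data.frame(stats))
  regions <- c("anterior", "septal", "inferior", "lateral", "apical",
               "basal", "apical5", "all")
  ss <- vapply(regions, function(r) summed_region(stats, r), numeric(1))
  cov <- tryCatch(total_cov(stats), error = function(e) NA_real_)
  structure(list(
    summed_suv = ss,
    total_cardiac_suv = ss[["all"]],
    cov = cov,
    pct_ds = percent_ds(stats),
    pct_ba = percent_ba(stats)
  ), class = "regional_index_set")
}

#' @export
print.regional_index_set <- function(x, ...) {
  cat(sprintf("<regional_index_set> total %.2f | COV %.2f | %%DS %.2f | %%BA %.2f\n",
              x$total_cardiac_suv, x$cov, x$pct_ds, x$pct_ba))
  cat("  summed SUV:",
      paste(sprintf("%s %.2f", names(x$summed_suv), x$summed_suv),
            collapse = ", "), "\n")
  invisible(x)
}

#' Full regional analysis of an SUV volume
#'
#' Convenience pipeline: reslice the volume into short-axis slices, build
#' the polar map, compute per-segment statistics and derive the regional
#' index set.
#'
#' @param volume a [suv_volume] (or [activity_volume] in SUV-like units).
#' @param lv_axis,lv_center_mm,extent_mm,anterior reslicing geometry, see
#'   [reslice_short_axis()].
#' @param n_rays,n_rings polar-map resolution.
#' @param half_size_mm in-plane half-extent of the short-axis slices.
#' @param sd_type SD denominator, see [segment_stats()].
#' @param ... further arguments to [build_polar_map()].
#' @return List with `stack`, `polar_map`, `stats`, `indices`.
#' @export
cardiac_indices <- function(volume, lv_axis, lv_center_mm, extent_mm,
                            anterior = c(0, 1, 0), n_rays = 60,
                            n_rings = 30, half_size_mm = 100,
                            sd_type = "population", ...) {
  stack <- reslice_short_axis(volume, lv_axis, lv_center_mm, extent_mm,
                              anterior = anterior,
                              half_size_mm = half_size_mm)
  pm <- build_polar_map(stack, n_rays = n_rays, n_rings = n_rings, ...)
  st <- segment_stats(pm, sd_type = sd_type)
  list(stack = stack, polar_map = pm, stats = st,
       indices = compute_indices(st))
}

#' One-row data.frame of a regional index set
#'
#' Column layout mirrors the per-patient regional analysis table (values to
#' full precision; round on output if 2-decimal display is wanted).
#'
#' @param idx a `regional_index_set`.
#' @param id optional subject identifier.
#' @return A one-row data.frame.
#' @export
indices_as_row <- function(idx, id = NA) {
  data.frame(id = id,
             total_cardiac_suv = idx$total_cardiac_suv,
             cov = idx$cov,
             summed_basal = idx$summed_suv[["basal"]],
             summed_apical = idx$summed_suv[["apical5"]],
             summed_septal = idx$summed_suv[["septal"]],
             summed_lateral = idx$summed_suv[["lateral"]],
             pct_ds = idx$pct_ds,
             pct_ba = idx$pct_ba)
}
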