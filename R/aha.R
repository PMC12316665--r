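#' AHA 17-segment model helpers
#'
#' Segment numbering follows the standard American Heart Association left
#' ventricular model: segments 1-6 basal, 7-12 mid-cavity (six 60 degree
#' sectors each), 13-16 apical (four 90 degree sectors), 17 the apex cap.
#' The angular origin (theta = 0) is the anterior wall; theta increases
#' toward the septum, so the septal wall sits at 90 degrees and the lateral
#' wall at 270 degrees.
#'
#' @name aha17
NULL

# segment lists for the two regional grouping schemes
.aha_regions <- list(
  anterior = c(1L, 7L, 13L),
  septal   = c(2L, 3L, 8L, 9L, 14L),
  inferior = c(4L, 10L, 15L),
  lateral  = c(5L, 6L, 11L, 12L, 16L),
  apical   = 17L,              # five-region scheme: apex cap only
  basal    = 1:12,             # two-region scheme
  apical5  = 13:17,            # two-region scheme
  all      = 1:17
)

#' Segments belonging to a named myocardial region
#'
#' Two grouping schemes are supported. The five-region scheme splits the
#' ventricle into anterior (1, 7, 13), septal (2, 3, 8, 9, 14), inferior
#' (4, 10, 15), lateral (5, 6, 11, 12, 16) and apical (17). The two-region
#' scheme uses basal (1-12) versus apical5 (13-17). `"all"` returns 1-17.
#'
#' @param region region name.
#' @return Integer vector of AHA segment ids.
#' @export
aha_region_segments <- function(region) {
  region <- match.arg(region, names(.aha_regions))
  .aha_regions[[region]]
}

# sector index for basal/mid rings: 6 sectors of 60 degrees, segment 1
# (anterior) centered at theta = 0, numbering increasing toward the septum
aha_sector6 <- function(theta) {
  as.integer(((theta + pi / 6) %% (2 * pi)) %/% (pi / 3)) + 1L
}

# sector index for apical rings: 4 sectors of 90 degrees, segment 13
# (anterior) centered at theta = 0
aha_sector4 <- function(theta) {
  as.integer(((theta + pi / 4) %% (2 * pi)) %/% (pi / 2)) + 13L
}

#' AHA segment id from long-axis level and circumferential angle
#'
#' @param level one of `"basal"`, `"mid"`, `"apical"`, `"apex"`.
#' @param theta circumferential angle in radians, 0 = anterior wall,
#'   increasing toward the septum.
#' @return Integer segment id(s) in 1..17.
#' @export
aha_segment <- function(level, theta) {
  switch(level,
    basal  = aha_sector6(theta),
    mid    = aha_sector6(theta) + 6L,
    apical = aha_sector4(theta),
    apex   = rep(17L, length(theta)),
    stop("unknown level: ", level)
  )
}

# orthonormal LV frame: a = unit long axis (apex -> base), e2 = anterior
# direction projected orthogonal to a, e1 chosen so that -e1 is septal
# (theta = atan2(<p,-e1>, <p,e2>) places the septum at +90 degrees)
lv_frame <- function(lv_axis, anterior) {
  a <- lv_axis / sqrt(sum(lv_axis^2))
  n0 <- anterior - a * sum(anterior * a)
  if (sqrt(sum(n0^2)) < 1e-8)
    stop("anterior reference must not be parallel to lv_axis")
  e2 <- n0 / sqrt(sum(n0^2))
  e1 <- c(e2[2] * a[3] - e2[3] * a[2],
          e2[3] * a[1] - e2[1] * a[3],
          e2[1] * a[2] - e2[2] * a[1])   # cross(e2, a)
  rbind(e1 = e1, e2 = e2, a = a)
}
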