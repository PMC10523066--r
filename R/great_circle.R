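## Geographic-range proxy: maximum great-circle distance among a genus's
## occurrences within one stage.

EARTH_RADIUS_KM <- 6371.0

#' Maximum great-circle distance among a set of points
#'
#' Largest haversine distance (sphere of radius 6371 km) over all pairs of
#' the supplied longitude/latitude points, computed with the vectorized
#' haversine formula over the full pair matrix. Callers are expected to have
#' reduced to distinct points first; with fewer than two distinct points the
#' range convention is 1 km and this function is not called.
#'
#' @param points Two-column matrix or data.frame of (lng, lat) in decimal
#'   degrees.
#' @return Maximum pairwise distance in km.
#' @examples
#' max_great_circle_km(cbind(c(0, 180), c(0, 0)))  # half circumference
#' @export
max_great_circle_km <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must have two columns (lng, lat)")
  if (nrow(pts) < 2L) stop("need at least 2 distinct points")
  if (any(abs(pts[, 1L]) > 180 | abs(pts[, 2L]) > 90) || any(!is.finite(pts))) {
    stop("invalid coordinates: lng must lie in [-180, 180], lat in [-90, 90]")
  }
  lam <- pts[, 1L] * (pi / 180)
  ph <- pts[, 2L] * (pi / 180)
  a <- sin(outer(ph, ph, "-") / 2)^2 +
    (cos(ph) %o% cos(ph)) * sin(outer(lam, lam, "-") / 2)^2
  max(2 * EARTH_RADIUS_KM * asin(sqrt(pmin(a, 1))))
}

## distinct-point test after rounding to 4 decimal places (PBDB precision)
distinct_points <- function(lng, lat) {
  unique(cbind(round(lng, 4L), round(lat, 4L)))
}
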