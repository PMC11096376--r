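# Great-circle distances between breeding and non-breeding sites.

# IUGG mean Earth radius, km.
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere. Used to derive migration distances
#' between breeding and non-breeding coordinates. Vectorized; all four
#' coordinate arguments are recycled to a common length.
#'
#' @param lat1,lon1 first point, decimal degrees.
#' @param lat2,lon2 second point, decimal degrees.
#' @param radius sphere radius in km (default the IUGG mean radius,
#'   6371.0088 km).
#' @return distances in km, in `[0, pi * radius]`.
#' @examples
#' great_circle_km(0, 0, 1, 0)   # ~111.195 km, one degree of latitude
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2, radius = EARTH_RADIUS_KM) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  radius * 2 * asin(sqrt(a))
}

check_coords <- function(lat, lon) {
  if (anyNA(lat) || anyNA(lon)) stop("coordinates contain missing values")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  invisible(TRUE)
}

# Longitude separation (degrees, >= 0) between two latitudes that yields a
# given great-circle distance; used by the synthetic generator to place
# non-breeding sites so the drawn distance is reproduced. Inverts the
# spherical law of cosines; the argument is clamped so a slightly
# infeasible distance maps to the nearest feasible geometry.
delta_lon_for_distance <- function(lat1, lat2, d_km, radius = EARTH_RADIUS_KM) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  cosang <- cos(d_km / radius)
  x <- (cosang - sin(p1) * sin(p2)) / (cos(p1) * cos(p2))
  x <- pmin(pmax(x, -1), 1)
  acos(x) * 180 / pi
}
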