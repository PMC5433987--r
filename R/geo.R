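#' Great-circle distance between points, km
#'
#' Haversine distance on a sphere. Vectorised over all four coordinate
#' arguments (recycled to common length). At the scales the pipeline works
#' with (tens of km) the spherical approximation error is negligible and no
#' map projection is used anywhere.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @param radius_km Sphere radius, km.
#' @return Numeric vector of distances in km.
#' @examples
#' dist_haversine_km(0, 0, 0, 1) # one degree of latitude, ~111.2 km
#' @export
dist_haversine_km <- function(lon1, lat1, lon2, lat2, radius_km = 6371) {
  check_lonlat(lon1, lat1)
  check_lonlat(lon2, lat2)
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  # clamp against rounding just above 1 for near-antipodal points
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon) | !is.finite(lat))) {
    abort("Non-finite coordinates.")
  }
  if (any(lat < -90 | lat > 90)) abort("Latitude outside [-90, 90].")
  if (any(lon < -180 | lon >= 360)) abort("Longitude outside [-180, 360).")
  invisible(TRUE)
}

#' Per-fix ground speed along a track, km/hr
#'
#' Backward-difference speed: the speed assigned to fix i is the great-circle
#' distance from fix i-1 divided by the elapsed time. The first fix of a
#' track has no previous segment and copies the speed of the segment that
#' follows it, so attendance classification is defined at every fix.
#'
#' @param time POSIXct vector, strictly increasing.
#' @param lon,lat Coordinates in decimal degrees.
#' @param radius_km Sphere radius, km.
#' @return Numeric vector of speeds, km/hr, same length as the input.
#' @export
ground_speed_kmh <- function(time, lon, lat, radius_km = 6371) {
  n <- length(time)
  stopifnot(length(lon) == n, length(lat) == n)
  if (n == 1) return(NA_real_)
  dt_hr <- as.numeric(difftime(time[-1], time[-n], units = "hours"))
  if (any(dt_hr <= 0)) abort("Timestamps must be strictly increasing.")
  d <- dist_haversine_km(lon[-n], lat[-n], lon[-1], lat[-1], radius_km)
  v <- d / dt_hr
  c(v[1], v)
}

#' Move a point a given distance along a bearing
#'
#' Spherical destination-point formula; used by the track simulators.
#'
#' @param lon,lat Start coordinates, degrees.
#' @param bearing_deg Bearing clockwise from north, degrees.
#' @param dist_km Distance, km.
#' @param radius_km Sphere radius, km.
#' @return A list with `lon` and `lat` vectors.
#' @export
move_point <- function(lon, lat, bearing_deg, dist_km, radius_km = 6371) {
  to_rad <- pi / 180
  phi1 <- lat * to_rad
  lam1 <- lon * to_rad
  theta <- bearing_deg * to_rad
  delta <- dist_km / radius_km
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(
    sin(theta) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  list(
    lon = ((lam2 / to_rad + 540) %% 360) - 180,
    lat = phi2 / to_rad
  )
}

#' Point-in-polygon test for a lon/lat ring
#'
#' Even-odd ray casting in plain lon/lat coordinates, with points lying
#' exactly on an edge or vertex counted as inside. Adequate for the modest,
#' convex-ish study-region polygons this package works with; not intended
#' for polygons crossing the antimeridian.
#'
#' @param lon,lat Point coordinates (vectorised).
#' @param ring Data frame with `lon`, `lat` columns; closed implicitly.
#' @return Logical vector.
#' @export
point_in_ring <- function(lon, lat, ring) {
  rx <- ring$lon
  ry <- ring$lat
  # drop an explicit closing vertex
  nr <- length(rx)
  if (rx[1] == rx[nr] && ry[1] == ry[nr]) {
    rx <- rx[-nr]
    ry <- ry[-nr]
    nr <- nr - 1
  }
  vapply(seq_along(lon), function(i) {
    x <- lon[i]
    y <- lat[i]
    inside <- FALSE
    j <- nr
    for (k in seq_len(nr)) {
      xj <- rx[j]; yj <- ry[j]; xk <- rx[k]; yk <- ry[k]
      # on-segment check: boundary counts as inside
      cross <- (x - xj) * (yk - yj) - (y - yj) * (xk - xj)
      if (abs(cross) < 1e-12 &&
          x >= min(xj, xk) - 1e-12 && x <= max(xj, xk) + 1e-12 &&
          y >= min(yj, yk) - 1e-12 && y <= max(yj, yk) + 1e-12) {
        return(TRUE)
      }
      if ((yk > y) != (yj > y)) {
        xint <- xk + (y - yk) * (xj - xk) / (yj - yk)
        if (x < xint) inside <- !inside
      }
      j <- k
    }
    inside
  }, logical(1))
}
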