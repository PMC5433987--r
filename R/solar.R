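#' Apparent solar elevation
#'
#' Solar elevation angle above the horizon, in degrees, for a UTC instant and
#' a position, using the NOAA solar-position equations (Meeus-style truncated
#' series for the solar coordinates and the equation of time) plus the
#' standard atmospheric-refraction correction. Accuracy is a few hundredths
#' of a degree over the 1950-2050 range, far tighter than the civil-twilight
#' day/night split (-6 degrees) it is used for.
#'
#' @param time POSIXct vector (converted to UTC).
#' @param lon,lat Position in decimal degrees.
#' @return Numeric vector of apparent elevations, degrees.
#' @examples
#' # local solar noon at the Greenwich equator on an equinox: sun near zenith
#' solar_elevation(as.POSIXct("2012-03-20 12:07:00", tz = "UTC"), 0, 0)
#' @export
solar_elevation <- function(time, lon, lat) {
  check_lonlat(lon, lat)
  t_utc <- as.POSIXct(time, tz = "UTC")
  # Julian day from Unix epoch (1970-01-01 00:00 UTC = JD 2440587.5)
  jd <- as.numeric(t_utc) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525 # Julian centuries from J2000.0

  geom_mean_long <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  geom_mean_anom <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)

  deg2rad <- pi / 180
  m <- geom_mean_anom * deg2rad
  eq_centre <- sin(m) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * m) * (0.019993 - 0.000101 * jc) +
    sin(3 * m) * 0.000289
  true_long <- geom_mean_long + eq_centre
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * deg2rad)

  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  obliq_corr <- mean_obliq + 0.00256 * cos(omega * deg2rad)

  declin <- asin(sin(obliq_corr * deg2rad) * sin(app_long * deg2rad)) / deg2rad

  vary <- tan(obliq_corr / 2 * deg2rad)^2
  l0 <- geom_mean_long * deg2rad
  eq_time <- 4 / deg2rad * (
    vary * sin(2 * l0) - 2 * ecc * sin(m) +
      4 * ecc * vary * sin(m) * cos(2 * l0) -
      0.5 * vary^2 * sin(4 * l0) - 1.25 * ecc^2 * sin(2 * m)
  ) # minutes

  minutes_utc <- (jd + 0.5 - floor(jd + 0.5)) * 1440
  true_solar_time <- (minutes_utc + eq_time + 4 * lon) %% 1440
  hour_angle <- true_solar_time / 4 - 180
  hour_angle <- ifelse(hour_angle < -180, hour_angle + 360, hour_angle)

  phi <- lat * deg2rad
  delta <- declin * deg2rad
  cos_zen <- sin(phi) * sin(delta) +
    cos(phi) * cos(delta) * cos(hour_angle * deg2rad)
  zen <- acos(pmin(1, pmax(-1, cos_zen))) / deg2rad
  elev <- 90 - zen

  elev + refraction_deg(elev)
}

# NOAA atmospheric refraction correction, degrees, as a function of the
# geometric (airless) elevation in degrees
refraction_deg <- function(elev) {
  corr <- numeric(length(elev))
  te <- tan(pmax(elev, -9) * pi / 180)
  hi <- elev > 85
  band1 <- !hi & elev > 5
  band2 <- !hi & !band1 & elev > -0.575
  band3 <- !hi & !band1 & !band2
  corr[band1] <- (58.1 / te[band1] - 0.07 / te[band1]^3 +
    0.000086 / te[band1]^5) / 3600
  e2 <- elev[band2]
  corr[band2] <- (1735 + e2 * (-518.2 + e2 * (103.4 +
    e2 * (-12.79 + e2 * 0.711)))) / 3600
  corr[band3] <- (-20.774 / te[band3]) / 3600
  corr
}

#' Daylight flag at bird fixes
#'
#' `TRUE` where the apparent solar elevation exceeds the configured daylight
#' threshold (civil twilight, -6 degrees, by default).
#'
#' @param time POSIXct vector.
#' @param lon,lat Position, degrees.
#' @param params A [analysis_params()] object.
#' @return Logical vector.
#' @export
is_daylight <- function(time, lon, lat, params = analysis_params()) {
  solar_elevation(time, lon, lat) > params$daylight_elev_deg
}
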