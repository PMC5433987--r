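#' Analysis parameters for bird-vessel interaction segmentation
#'
#' Bundles every threshold used by the pipeline in a single validated record.
#' Defaults follow the standard operational definitions for wandering
#' albatross-longliner interactions near a breeding colony: a bird location is
#' within *attraction range* of a vessel when their great-circle distance is
#' below 30 km (the approximate visual detection limit for a flying
#' albatross); it is an *attendance* location when it lies within 3 km of a
#' vessel with a ground speed below 10 km/hr (a bird sitting on the water next
#' to the boat); an *encounter event* tolerates up to four consecutive
#' out-of-range fixes (about 1 hr at 15-min sampling, the "time-to-return"
#' allowance) before being split in two.
#'
#' All distance comparisons are strict (`distance < attraction_km`), as are
#' the speed rules: sitting requires `speed < sit_speed_kmh` and flying
#' requires `speed > fly_speed_kmh`, so a fix exactly at 10 km/hr is neither.
#'
#' @param attraction_km Attraction range radius, km. A bird fix is "in range"
#'   when at least one vessel is closer than this.
#' @param attendance_km Attendance radius, km. Must be below `attraction_km`.
#' @param sit_speed_kmh Speed below which a bird is considered sitting, km/hr.
#' @param fly_speed_kmh Speed above which a bird is considered flying, km/hr.
#' @param time_to_return_locs Maximum number of consecutive out-of-range bird
#'   fixes tolerated inside one encounter event.
#' @param bird_dt Nominal bird sampling interval, minutes.
#' @param vessel_dt Vessel interpolation grid step, minutes.
#' @param match_tol Maximum bird-vessel time offset for a spatiotemporal
#'   match, minutes.
#' @param daylight_elev_deg Solar elevation (degrees) above which it is "day";
#'   the default -6 is civil twilight.
#' @param earth_radius_km Sphere radius used for great-circle distances.
#' @param shelf_polygon Closed ring of the study-region polygon: a data frame
#'   with columns `lon`, `lat` (first and last vertex may coincide; the ring
#'   is closed implicitly otherwise).
#' @param colony Colony position: a list or one-row data frame with `lon`,
#'   `lat`.
#' @param colony_radius_km Radius within which a trip is considered to start
#'   and end at the colony.
#' @param alpha Significance level used when pruning model interaction terms.
#' @param nest_mass_loss_rate Mass-loss rate on the nest, g/day, used to
#'   correct departure and return masses.
#'
#' @return An object of class `vb_params`: a named list of the validated
#'   parameters.
#' @examples
#' p <- analysis_params()
#' p$attraction_km
#' @export
analysis_params <- function(attraction_km = 30,
                            attendance_km = 3,
                            sit_speed_kmh = 10,
                            fly_speed_kmh = 10,
                            time_to_return_locs = 4,
                            bird_dt = 15,
                            vessel_dt = 10,
                            match_tol = 5,
                            daylight_elev_deg = -6,
                            earth_radius_km = 6371,
                            shelf_polygon = crozet_like_shelf(),
                            colony = list(lon = 51.86, lat = -46.42),
                            colony_radius_km = 10,
                            alpha = 0.05,
                            nest_mass_loss_rate = 0) {
  stopifnot(
    is.numeric(attraction_km), attraction_km > 0,
    is.numeric(attendance_km), attendance_km > 0,
    is.numeric(sit_speed_kmh), sit_speed_kmh > 0,
    is.numeric(fly_speed_kmh), fly_speed_kmh > 0,
    is.numeric(time_to_return_locs), time_to_return_locs >= 0,
    is.numeric(bird_dt), bird_dt > 0,
    is.numeric(vessel_dt), vessel_dt > 0,
    is.numeric(match_tol), match_tol > 0,
    is.numeric(earth_radius_km), earth_radius_km > 0,
    is.numeric(alpha), alpha > 0, alpha <= 1
  )
  if (attendance_km >= attraction_km) {
    abort("`attendance_km` must be smaller than `attraction_km`.")
  }
  shelf_polygon <- as_tibble(shelf_polygon)
  if (!all(c("lon", "lat") %in% names(shelf_polygon)) ||
      nrow(shelf_polygon) < 3) {
    abort("`shelf_polygon` must be a data frame with >= 3 rows of lon/lat.")
  }
  colony <- as.list(colony)
  if (!all(c("lon", "lat") %in% names(colony))) {
    abort("`colony` must have `lon` and `lat`.")
  }
  structure(
    list(
      attraction_km = attraction_km,
      attendance_km = attendance_km,
      sit_speed_kmh = sit_speed_kmh,
      fly_speed_kmh = fly_speed_kmh,
      time_to_return_locs = as.integer(time_to_return_locs),
      bird_dt = bird_dt,
      vessel_dt = vessel_dt,
      match_tol = match_tol,
      daylight_elev_deg = daylight_elev_deg,
      earth_radius_km = earth_radius_km,
      shelf_polygon = shelf_polygon,
      colony = colony,
      colony_radius_km = colony_radius_km,
      alpha = alpha,
      nest_mass_loss_rate = nest_mass_loss_rate
    ),
    class = "vb_params"
  )
}

#' @export
print.vb_params <- function(x, ...) {
  cat("<vb_params>\n")
  cat(sprintf("  attraction range     : %g km\n", x$attraction_km))
  cat(sprintf("  attendance radius    : %g km\n", x$attendance_km))
  cat(sprintf("  sitting / flying     : < %g / > %g km/hr\n",
              x$sit_speed_kmh, x$fly_speed_kmh))
  cat(sprintf("  time-to-return       : %d locations\n", x$time_to_return_locs))
  cat(sprintf("  bird / vessel step   : %g / %g min (match tol %g min)\n",
              x$bird_dt, x$vessel_dt, x$match_tol))
  cat(sprintf("  daylight threshold   : sun > %g deg\n", x$daylight_elev_deg))
  cat(sprintf("  colony               : (%.3f, %.3f), radius %g km\n",
              x$colony$lon, x$colony$lat, x$colony_radius_km))
  invisible(x)
}

#' A generic sub-Antarctic shelf polygon
#'
#' A simple rectangular lon/lat ring around a colony at roughly 46.4 S,
#' 51.9 E, standing in for the bathymetric shelf of the study region (which
#' is not recoverable from public data). Any user polygon with `lon`/`lat`
#' columns can replace it.
#'
#' @return A tibble with columns `lon`, `lat` describing a closed ring.
#' @export
crozet_like_shelf <- function() {
  tibble(
    lon = c(50.0, 54.0, 54.0, 50.0, 50.0),
    lat = c(-47.5, -47.5, -45.3, -45.3, -47.5)
  )
}

#' Read analysis parameters from a YAML configuration file
#'
#' The file may set any subset of [analysis_params()] arguments; unset fields
#' keep their defaults. `shelf_polygon` may be given inline as `lon`/`lat`
#' lists or as a path (relative to the config file) to a GeoJSON polygon.
#'
#' @param path Path to a YAML file.
#' @return A `vb_params` object.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$shelf_polygon)) {
    sp <- cfg$shelf_polygon
    if (is.character(sp)) {
      sp_path <- if (file.exists(sp)) sp else file.path(dirname(path), sp)
      cfg$shelf_polygon <- read_region(sp_path)
    } else {
      cfg$shelf_polygon <- tibble(
        lon = as.numeric(sp$lon),
        lat = as.numeric(sp$lat)
      )
    }
  }
  if (!is.null(cfg$colony)) cfg$colony <- as.list(cfg$colony)
  do.call(analysis_params, cfg)
}
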