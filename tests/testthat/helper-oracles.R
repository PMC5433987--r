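# Independent oracles used across the suite. These deliberately take a
# different algorithmic route from the package code they check.

# Maximal tolerated runs by forward greedy scan (vs the package's
# index-difference splitting): walk the sequence, extending an open event
# while the out-of-range gap since the last in-range fix stays within tol.
brute_force_runs <- function(in_range, tol) {
  starts <- integer()
  ends <- integer()
  open <- FALSE
  gap <- 0L
  for (i in seq_along(in_range)) {
    if (in_range[i]) {
      if (!open) {
        starts <- c(starts, i)
        open <- TRUE
      }
      ends[length(starts)] <- i
      gap <- 0L
    } else if (open) {
      gap <- gap + 1L
      if (gap > tol) {
        open <- FALSE
        gap <- 0L
      }
    }
  }
  data.frame(start = starts, end = ends)
}

# Spherical law of cosines: a closed form independent of the haversine
slc_km <- function(lon1, lat1, lon2, lat2, r = 6371) {
  d2r <- pi / 180
  ca <- sin(lat1 * d2r) * sin(lat2 * d2r) +
    cos(lat1 * d2r) * cos(lat2 * d2r) * cos((lon2 - lon1) * d2r)
  r * acos(pmin(1, pmax(-1, ca)))
}

# Apparent solar elevations computed with an independent published solar
# calculator (the astral library) at 46 S, 52 E; frozen reference values.
solar_reference <- data.frame(
  time = as.POSIXct(c(
    "2012-01-15 06:00:00", "2012-01-15 08:30:00", "2012-01-15 12:45:00",
    "2012-01-15 18:00:00", "2012-01-15 20:30:00", "2012-03-01 04:00:00",
    "2012-03-01 15:00:00", "2012-06-21 08:30:00", "2012-12-21 08:30:00",
    "2013-02-10 22:00:00"
  ), tz = "UTC"),
  lon = 52, lat = -46,
  elev = c(48.9846, 65.1056, 35.0819, -13.5466, -22.8252,
           18.5052, 2.7579, 20.6012, 67.4427, -27.6628)
)

# A small, quick scenario for property tests
tiny_scenario <- function(seed, n_birds = 2, n_vessels = 2,
                          dur = c(1.5, 3), n_days = 5, ...) {
  cfg <- scenario_config(
    n_birds = n_birds, n_trips_per_bird = 1,
    trip_duration_range = dur, n_vessels = n_vessels, n_days = n_days, ...
  )
  simulate_scenario(cfg, seed = seed)
}

# Build a synthetic matched-locations table directly (no simulator), with
# full control over distances/speeds/daylight; one trip.
matched_frame <- function(nearest_distance,
                          bird_speed = 50,
                          is_daylight = TRUE,
                          attendance_km = 3, attraction_km = 30,
                          sit_speed = 10,
                          t0 = as.POSIXct("2012-01-15 06:00:00", tz = "UTC"),
                          trip_id = "T1", bird_id = "B1") {
  n <- length(nearest_distance)
  bird_speed <- rep_len(bird_speed, n)
  is_daylight <- rep_len(is_daylight, n)
  in_attr <- !is.na(nearest_distance) & nearest_distance < attraction_km
  tibble::tibble(
    bird_id = bird_id, trip_id = trip_id,
    timestamp = t0 + (seq_len(n) - 1) * 900,
    lat = -46.5, lon = 52,
    bird_speed = bird_speed,
    n_boats_in_range = as.integer(in_attr),
    vessels_in_range = ifelse(in_attr, "V01", ""),
    nearest_vessel_id = ifelse(is.na(nearest_distance), NA, "V01"),
    nearest_distance = nearest_distance,
    nearest_activity = ifelse(is.na(nearest_distance), NA, "transit"),
    is_daylight = is_daylight,
    in_attraction = in_attr,
    is_attendance = in_attr & nearest_distance < attendance_km &
      bird_speed < sit_speed
  )
}
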