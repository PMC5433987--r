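#' Sensitivity sweep over attraction range and time-to-return
#'
#' Re-runs the encounter segmentation and the headline attendance statistics
#' for every combination of attraction radius and time-to-return allowance,
#' reusing the matched locations (the spatiotemporal join and the 3-km
#' attendance classification are computed once; only the attraction gate and
#' the gap tolerance change). Time-to-return values are given in hours and
#' converted to fix counts with `round(hours * 60 / bird_dt)`.
#'
#' The default grid spans radii of 15-30 km and allowances of 0.5-24 hr.
#' The cell at the default parameters (30 km, 1 hr) reproduces the main
#' pipeline exactly.
#'
#' @param matched Output of [match_locations()].
#' @param attraction_km Numeric vector of radii, km.
#' @param time_to_return_hr Numeric vector of allowances, hours.
#' @param params An [analysis_params()].
#' @return A tibble with one row per grid cell: `attraction_km,
#'   time_to_return_hr, time_to_return_locs, n_encounters,
#'   prop_trips_with_encounter, p_attend, mean_attend_locs,
#'   mean_attend_prop`. Encounter statistics use retained (daylight-flying)
#'   events; attendance means are over attended events.
#' @export
sweep_thresholds <- function(matched,
                             attraction_km = c(15, 20, 25, 30),
                             time_to_return_hr = c(0.5, 1, 2, 6, 12, 24),
                             params = analysis_params()) {
  if (any(time_to_return_hr * 60 < params$bird_dt)) {
    abort("Time-to-return values below one fix interval are not allowed.")
  }
  if (any(attraction_km < params$attendance_km)) {
    abort("Attraction radii below the attendance radius are not allowed.")
  }
  n_trips <- n_distinct(matched$trip_id)
  grid <- tidyr::expand_grid(
    attraction_km = attraction_km,
    time_to_return_hr = time_to_return_hr
  )
  out <- purrr::pmap_dfr(grid, function(attraction_km, time_to_return_hr) {
    ttr <- as.integer(round(time_to_return_hr * 60 / params$bird_dt))
    p2 <- params
    p2$attraction_km <- attraction_km
    p2$time_to_return_locs <- ttr
    m2 <- mutate(matched,
      in_attraction = !is.na(.data$nearest_distance) &
        .data$nearest_distance < attraction_km,
      is_attendance = .data$is_attendance & .data$in_attraction
    )
    ev <- segment_encounters(m2, p2) |>
      filter_daylight_flying(p2) |>
      filter(.data$retained_daylight)
    att <- filter(ev, .data$has_attendance)
    tibble(
      attraction_km = attraction_km,
      time_to_return_hr = time_to_return_hr,
      time_to_return_locs = ttr,
      n_encounters = nrow(ev),
      prop_trips_with_encounter = n_distinct(ev$trip_id) / n_trips,
      p_attend = if (nrow(ev)) mean(ev$has_attendance) else NA_real_,
      mean_attend_locs = if (nrow(att)) mean(att$n_attendance) else NA_real_,
      mean_attend_prop = if (nrow(att)) {
        mean(att$n_attendance / att$n_locations)
      } else {
        NA_real_
      }
    )
  })
  class(out) <- c("vb_sweep", class(out))
  out
}
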