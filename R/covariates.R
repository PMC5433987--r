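#' Time from the start of an encounter to the closest fishing activity
#'
#' Zero when any of the event's vessels is inside a fishing operation
#' (setting or hauling) at the moment the bird enters attraction range;
#' otherwise the smaller of (time since the latest operation that ended
#' before the encounter start) and (time until the next operation to start),
#' minimised over the event's vessels. Sides with no operation are ignored;
#' a vessel set with no operations on record at all yields `NA`.
#'
#' @param event_start POSIXct instant the encounter starts.
#' @param ops Operations tibble restricted (by the caller or via
#'   `vessel_ids`) to the event's vessels.
#' @param vessel_ids Optional character vector (or single comma-separated
#'   string) of the event's vessels; when given, `ops` is filtered to them.
#' @return Hours (numeric scalar), `NA_real_` when no operation exists.
#' @export
time_to_fishing <- function(event_start, ops, vessel_ids = NULL) {
  if (!is.null(vessel_ids)) {
    ids <- unlist(strsplit(vessel_ids, ",", fixed = TRUE))
    ops <- ops[ops$vessel_id %in% ids, ]
  }
  if (!nrow(ops)) return(NA_real_)
  t0 <- as.numeric(event_start)
  s <- as.numeric(ops$t_start)
  e <- as.numeric(ops$t_end)
  if (any(s <= t0 & t0 < e)) return(0)
  prev_end <- suppressWarnings(max(e[e <= t0]))
  next_start <- suppressWarnings(min(s[s > t0]))
  min(t0 - prev_end, next_start - t0, na.rm = FALSE) / 3600
}

#' Proportion of an encounter event spent with the vessel in operation
#'
#' The fraction of the event's fixes whose matched nearest vessel is
#' labelled `setting` or `hauling`.
#'
#' @param event_locs The matched-location rows of one event (all fixes from
#'   first to last in-range location, inclusive).
#' @return Fraction in `[0, 1]`.
#' @export
prop_fishing <- function(event_locs) {
  if (!nrow(event_locs)) abort("Empty event.")
  mean(!is.na(event_locs$nearest_activity) &
         event_locs$nearest_activity %in% c("setting", "hauling"))
}

#' Attendance metrics of an encounter event
#'
#' For an event containing attendance: the number of attendance fixes, the
#' corresponding absolute duration given the sampling interval, the
#' proportion of the event's locations spent attending, and the mean
#' bird-vessel distance over the attendance fixes, in metres.
#'
#' @param event_locs Matched-location rows of one event.
#' @param bird_dt Sampling interval, minutes.
#' @return A one-row tibble: `duration_locs, duration_hr, prop_of_event,
#'   mean_distance_m`.
#' @export
attendance_metrics <- function(event_locs, bird_dt = 15) {
  att <- event_locs[event_locs$is_attendance, ]
  if (!nrow(att)) {
    abort("attendance_metrics() called on an event without attendance.")
  }
  tibble(
    duration_locs = nrow(att),
    duration_hr = nrow(att) * bird_dt / 60,
    prop_of_event = nrow(att) / nrow(event_locs),
    mean_distance_m = mean(att$nearest_distance) * 1000
  )
}

# matched rows of one event (inclusive window, same trip)
event_slice <- function(matched, ev) {
  matched[matched$trip_id == ev$trip_id &
            matched$timestamp >= ev$t_start &
            matched$timestamp <= ev$t_end, ]
}

#' Per-event covariates and response variables
#'
#' Combines the segmentation output with operation records and bird metadata
#' into the event-level analysis table: the activity covariates
#' ([time_to_fishing()] at the event start and [prop_fishing()] over the
#' event), the average number of vessels in range, the season grouping
#' (`2013` against `2011-12`, the low- vs normal-fleet seasons), and the
#' attendance metrics for events that contain attendance.
#'
#' @param events Output of [filter_daylight_flying()] (or
#'   [segment_encounters()]; a missing `retained_daylight` column is treated
#'   as all-retained).
#' @param matched Output of [match_locations()].
#' @param ops Operations tibble.
#' @param bird_meta Tibble with `bird_id, sex, age, year`.
#' @param params An [analysis_params()].
#' @return `events` with columns `time_to_fishing, prop_fishing, year_group,
#'   sex, age` and (where `has_attendance`) `duration_locs, duration_hr,
#'   prop_of_event, mean_distance_m`.
#' @export
event_covariates <- function(events, matched, ops, bird_meta,
                             params = analysis_params()) {
  if (!nrow(events)) {
    return(mutate(events,
      time_to_fishing = numeric(), prop_fishing = numeric(),
      year_group = character(), duration_locs = integer(),
      duration_hr = numeric(), prop_of_event = numeric(),
      mean_distance_m = numeric()
    ))
  }
  if (!"retained_daylight" %in% names(events)) {
    events$retained_daylight <- TRUE
  }
  extra <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    sl <- event_slice(matched, ev)
    am <- if (ev$has_attendance) {
      attendance_metrics(sl, params$bird_dt)
    } else {
      tibble(duration_locs = 0L, duration_hr = 0,
             prop_of_event = 0, mean_distance_m = NA_real_)
    }
    tibble(
      time_to_fishing = time_to_fishing(ev$t_start, ops, ev$vessel_ids),
      prop_fishing = prop_fishing(sl)
    ) |>
      bind_cols(am)
  })
  events |>
    bind_cols(extra) |>
    left_join(select(bird_meta, "bird_id", "sex", "age", "year"),
              by = "bird_id") |>
    mutate(year_group = ifelse(.data$year == "2013", "2013", "2011-12"))
}

#' Trip-level summary statistics
#'
#' One row per trip: duration, maximum range from the colony, total
#' great-circle distance covered, the proportion of fixes over the shelf
#' polygon, the average number of vessels present over the shelf (evaluated
#' at the trip's fix instants), the number of retained encounter events, and
#' the attendance totals over retained events.
#'
#' @param matched Output of [match_locations()].
#' @param events Output of [filter_daylight_flying()] with covariates or
#'   not; only `retained_daylight`, `has_attendance` and `n_attendance` are
#'   used.
#' @param vessel_tracks Interpolated vessel tracks.
#' @param bird_meta Bird metadata tibble.
#' @param params An [analysis_params()].
#' @return A tibble with one row per trip (class columns from `bird_meta`
#'   joined in).
#' @export
trip_summary <- function(matched, events, vessel_tracks, bird_meta,
                         params = analysis_params()) {
  if (!"retained_daylight" %in% names(events) && nrow(events)) {
    events$retained_daylight <- TRUE
  }
  lk <- if (nrow(vessel_tracks)) vessel_lookup(vessel_tracks) else list()
  tol_s <- params$match_tol * 60

  boats_on_shelf_at <- function(tt) {
    if (!length(lk)) return(rep(0L, length(tt)))
    counts <- rep(0L, length(tt))
    for (vid in names(lk)) {
      l <- lk[[vid]]
      i <- findInterval(tt, l$t)
      lo <- pmin(pmax(i, 1L), length(l$t))
      hi <- pmin(i + 1L, length(l$t))
      j <- ifelse(abs(l$t[lo] - tt) <= abs(l$t[hi] - tt), lo, hi)
      ok <- abs(l$t[j] - tt) <= tol_s
      if (!any(ok)) next
      ok[ok] <- point_in_ring(l$lon[j[ok]], l$lat[j[ok]],
                              params$shelf_polygon)
      counts <- counts + as.integer(ok)
    }
    counts
  }

  ev_trip <- if (nrow(events)) {
    events |>
      filter(.data$retained_daylight) |>
      group_by(.data$trip_id) |>
      summarise(
        n_encounters = n(),
        any_attendance = any(.data$has_attendance),
        attendance_locs = sum(.data$n_attendance),
        .groups = "drop"
      )
  } else {
    tibble(trip_id = character(), n_encounters = integer(),
           any_attendance = logical(), attendance_locs = integer())
  }

  matched |>
    group_by(.data$bird_id, .data$trip_id) |>
    group_modify(function(df, key) {
      tt <- as.numeric(df$timestamp)
      seg <- dist_haversine_km(
        df$lon[-nrow(df)], df$lat[-nrow(df)],
        df$lon[-1], df$lat[-1], params$earth_radius_km
      )
      tibble(
        duration_days = as.numeric(difftime(max(df$timestamp),
                                            min(df$timestamp),
                                            units = "days")),
        max_range_km = max(dist_haversine_km(
          df$lon, df$lat, params$colony$lon, params$colony$lat,
          params$earth_radius_km
        )),
        total_distance_km = sum(seg),
        prop_on_shelf = mean(point_in_ring(df$lon, df$lat,
                                           params$shelf_polygon)),
        avg_boats_present = mean(boats_on_shelf_at(tt))
      )
    }) |>
    ungroup() |>
    left_join(ev_trip, by = "trip_id") |>
    mutate(
      n_encounters = ifelse(is.na(.data$n_encounters), 0L,
                            .data$n_encounters),
      any_attendance = ifelse(is.na(.data$any_attendance), FALSE,
                              .data$any_attendance),
      attendance_locs = ifelse(is.na(.data$attendance_locs), 0L,
                               .data$attendance_locs),
      attendance_time_hr = .data$attendance_locs * params$bird_dt / 60,
      attendance_prop_of_trip = .data$attendance_time_hr /
        (.data$duration_days * 24)
    ) |>
    left_join(select(bird_meta, "bird_id", "sex", "age", "year"),
              by = "bird_id")
}
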