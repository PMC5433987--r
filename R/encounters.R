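#' Segment encounter events with the time-to-return allowance
#'
#' An encounter event is a maximal run of consecutive bird fixes within
#' attraction range of at least one vessel, tolerating internal out-of-range
#' gaps of at most `params$time_to_return_locs` consecutive fixes (four, or
#' about one hour at 15-min sampling, by default). Events are trimmed to
#' start and end on in-range fixes, tolerated gap fixes count towards the
#' event length, and two events of the same trip are separated by more than
#' the allowance. Events are numbered chronologically within each trip.
#'
#' @param matched Output of [match_locations()] (any number of trips).
#' @param params An [analysis_params()].
#' @return A tibble with one row per event: `bird_id, trip_id, event_index,
#'   t_start, t_end, n_locations, n_attendance, has_attendance, vessel_ids,
#'   avg_boats_in_range, n_daylight_flying`.
#' @export
segment_encounters <- function(matched, params = analysis_params()) {
  empty <- tibble(
    bird_id = character(), trip_id = character(), event_index = integer(),
    t_start = as.POSIXct(character(), tz = "UTC"),
    t_end = as.POSIXct(character(), tz = "UTC"),
    n_locations = integer(), n_attendance = integer(),
    has_attendance = logical(), vessel_ids = character(),
    avg_boats_in_range = numeric(), n_daylight_flying = integer()
  )
  if (!nrow(matched)) return(empty)
  out <- matched |>
    arrange(.data$bird_id, .data$trip_id, .data$timestamp) |>
    group_by(.data$bird_id, .data$trip_id) |>
    group_modify(function(df, key) {
      runs <- tolerated_runs(df$in_attraction, params$time_to_return_locs)
      if (!nrow(runs)) return(empty[0, c(-1, -2)])
      purrr::pmap_dfr(runs, function(start, end) {
        sl <- df[start:end, ]
        ids <- unique(unlist(strsplit(
          sl$vessels_in_range[sl$vessels_in_range != ""], ",", fixed = TRUE
        )))
        tibble(
          t_start = sl$timestamp[1],
          t_end = sl$timestamp[nrow(sl)],
          n_locations = nrow(sl),
          n_attendance = sum(sl$is_attendance),
          has_attendance = any(sl$is_attendance),
          vessel_ids = paste(sort(ids), collapse = ","),
          avg_boats_in_range = mean(sl$n_boats_in_range),
          n_daylight_flying = sum(sl$is_daylight &
                                    !is.na(sl$bird_speed) &
                                    sl$bird_speed > params$fly_speed_kmh)
        )
      }) |>
        mutate(event_index = row_number(), .before = 1)
    }) |>
    ungroup() |>
    relocate("bird_id", "trip_id", "event_index")
  out
}

# maximal runs over a logical vector, merging across internal FALSE gaps of
# length <= tol; returns a tibble of start/end indices (trimmed to TRUEs)
tolerated_runs <- function(in_range, tol) {
  idx <- which(in_range)
  if (!length(idx)) return(tibble(start = integer(), end = integer()))
  gap <- diff(idx) - 1L # out-of-range fixes between consecutive in-range ones
  brk <- which(gap > tol)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  tibble(start = starts, end = ends)
}

#' Flag events retained by the daylight-flying filter
#'
#' An event is retained when it contains at least one fix that is both in
#' daylight (apparent solar elevation above `params$daylight_elev_deg`) and
#' flying (speed above `params$fly_speed_kmh`). Events without such a fix
#' (e.g. entirely nocturnal, all-sitting passes) are excluded from the
#' behavioural analyses; attendance fixes inside retained events count
#' regardless of their own day/night status.
#'
#' @param events Output of [segment_encounters()].
#' @param params An [analysis_params()].
#' @return `events` with a logical `retained_daylight` column.
#' @export
filter_daylight_flying <- function(events, params = analysis_params()) {
  mutate(events, retained_daylight = .data$n_daylight_flying >= 1L)
}
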