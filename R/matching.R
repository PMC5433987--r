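#' Join bird fixes to vessel tracks and classify each fix
#'
#' For every bird GPS fix and every vessel, selects the vessel grid point
#' closest in time, provided the offset is within `params$match_tol` (5 min
#' by default; with a 10-min vessel grid every bird fix inside a vessel's
#' track span matches exactly one point). A tie at exactly the tolerance on
#' both sides goes to the earlier vessel point. The fix is then annotated
#' with its ground speed (backward difference, see [ground_speed_kmh()]),
#' the nearest vessel and its distance and activity, a daylight flag
#' (apparent solar elevation above the civil-twilight threshold), and the
#' two behavioural classifications:
#'
#' * `in_attraction`: at least one matched vessel closer than
#'   `params$attraction_km`;
#' * `is_attendance`: the nearest vessel closer than `params$attendance_km`
#'   *and* bird speed below `params$sit_speed_kmh` (a bird sitting on the
#'   water beside the boat). Attendance implies attraction by construction.
#'
#' When several vessels are exactly equidistant-nearest the smallest
#' `vessel_id` wins, for determinism. A fix outside every vessel's span is
#' matched to no vessel and is simply out of range.
#'
#' @param bird_tracks Tibble `bird_id, trip_id, timestamp, lat, lon`.
#' @param vessel_tracks Interpolated tracks from
#'   [interpolate_vessel_tracks()].
#' @param params An [analysis_params()].
#' @return A tibble with one row per bird fix: the input columns plus
#'   `bird_speed`, `n_boats_in_range`, `nearest_vessel_id`,
#'   `nearest_distance`, `nearest_activity`, `is_daylight`, `in_attraction`,
#'   `is_attendance`.
#' @export
match_locations <- function(bird_tracks, vessel_tracks,
                            params = analysis_params()) {
  bird_tracks <- arrange(as_tibble(bird_tracks),
                         .data$bird_id, .data$trip_id, .data$timestamp)
  tol_s <- params$match_tol * 60

  vsplit <- if (nrow(vessel_tracks)) {
    split(vessel_tracks, vessel_tracks$vessel_id)
  } else {
    list()
  }
  vids <- sort(names(vsplit))

  bird_tracks |>
    group_by(.data$bird_id, .data$trip_id) |>
    group_modify(function(df, key) {
      n <- nrow(df)
      tt <- as.numeric(df$timestamp)
      speed <- if (n >= 2) {
        ground_speed_kmh(df$timestamp, df$lon, df$lat,
                         params$earth_radius_km)
      } else {
        rep(NA_real_, n)
      }
      nearest_d <- rep(Inf, n)
      nearest_v <- rep(NA_character_, n)
      nearest_a <- rep(NA_character_, n)
      n_in_range <- rep(0L, n)
      ids_in_range <- rep("", n)
      for (vid in vids) {
        tr <- vsplit[[vid]]
        vt <- as.numeric(tr$timestamp)
        i <- findInterval(tt, vt)
        lo <- pmin(pmax(i, 1L), length(vt))
        hi <- pmin(i + 1L, length(vt))
        d_lo <- abs(vt[lo] - tt)
        d_hi <- abs(vt[hi] - tt)
        # earlier point wins ties
        j <- ifelse(d_lo <= d_hi, lo, hi)
        dt <- pmin(d_lo, d_hi)
        ok <- dt <= tol_s
        if (!any(ok)) next
        d <- rep(Inf, n)
        d[ok] <- dist_haversine_km(df$lon[ok], df$lat[ok],
                                   tr$lon[j[ok]], tr$lat[j[ok]],
                                   params$earth_radius_km)
        inr <- d < params$attraction_km
        n_in_range <- n_in_range + as.integer(inr)
        ids_in_range[inr] <- ifelse(ids_in_range[inr] == "", vid,
                                    paste(ids_in_range[inr], vid, sep = ","))
        upd <- d < nearest_d # strict: earlier (smaller) vessel_id keeps ties
        nearest_d[upd] <- d[upd]
        nearest_v[upd] <- vid
        nearest_a[upd] <- tr$activity[j[upd]]
      }
      daylight <- solar_elevation(df$timestamp, df$lon, df$lat) >
        params$daylight_elev_deg
      in_attr <- is.finite(nearest_d) & nearest_d < params$attraction_km
      attend <- in_attr &
        nearest_d < params$attendance_km &
        !is.na(speed) & speed < params$sit_speed_kmh
      mutate(df,
        bird_speed = speed,
        n_boats_in_range = n_in_range,
        vessels_in_range = ids_in_range,
        nearest_vessel_id = nearest_v,
        nearest_distance = ifelse(is.finite(nearest_d), nearest_d, NA_real_),
        nearest_activity = nearest_a,
        is_daylight = daylight,
        in_attraction = in_attr,
        is_attendance = attend
      )
    }) |>
    ungroup() |>
    relocate("bird_id", "trip_id")
}
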