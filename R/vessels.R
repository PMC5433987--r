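#' Merge raw VMS fixes with fishing-operation endpoints
#'
#' Per vessel, forms the time-sorted union of the hourly VMS fixes and the
#' start/end positions of every fishing operation, so the operation endpoints
#' become extra source knots for interpolation. When a VMS fix and an
#' operation endpoint share a timestamp exactly, the operation point is kept
#' (it was recorded on deck at the moment of the manoeuvre).
#'
#' @param vms Tibble `vessel_id, timestamp, lat, lon`.
#' @param ops Tibble in the standard operations dialect (may be empty).
#' @return Tibble `vessel_id, timestamp, lat, lon, source` with `source`
#'   either `"vms"` or `"operation"`, sorted by vessel and time.
#' @export
merge_vms_operations <- function(vms, ops) {
  vms <- mutate(as_tibble(vms), source = "vms")
  if (nrow(ops)) {
    unknown <- setdiff(unique(ops$vessel_id), unique(vms$vessel_id))
    if (length(unknown)) {
      abort(sprintf("Operations reference unknown vessel(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    op_pts <- bind_rows(
      transmute(ops, vessel_id = .data$vessel_id,
                timestamp = .data$t_start,
                lat = .data$lat_start, lon = .data$lon_start),
      transmute(ops, vessel_id = .data$vessel_id,
                timestamp = .data$t_end,
                lat = .data$lat_end, lon = .data$lon_end)
    ) |>
      mutate(source = "operation")
    out <- bind_rows(vms, op_pts)
  } else {
    out <- vms
  }
  out |>
    mutate(.op_first = .data$source != "operation") |>
    arrange(.data$vessel_id, .data$timestamp, .data$.op_first) |>
    # duplicate timestamps: operation point wins
    distinct(.data$vessel_id, .data$timestamp, .keep_all = TRUE) |>
    select("vessel_id", "timestamp", "lat", "lon", "source")
}

#' Interpolate merged vessel fixes onto a regular grid and label activity
#'
#' Produces one position every `vessel_dt` minutes between each vessel's
#' first and last source fix, by linear interpolation of longitude and
#' latitude in time; source fixes that fall exactly on the grid pass through
#' unchanged and are flagged as non-interpolated. Each grid point is labelled
#' `setting` or `hauling` when its timestamp lies inside an operation
#' interval of that vessel (`t_start <= t < t_end`), otherwise `transit`.
#' The grid is anchored at the first source fix's timestamp rounded down to
#' a whole `vessel_dt` boundary (UTC), so grids are reproducible across
#' runs; there is no extrapolation beyond the track span.
#'
#' @param vms Raw VMS tibble, or the output of [merge_vms_operations()].
#' @param ops Operations tibble (used for both merging, when `vms` is raw,
#'   and activity labelling).
#' @param vessel_dt Grid step, minutes.
#' @return Tibble `vessel_id, timestamp, lat, lon, activity, interpolated`.
#' @export
interpolate_vessel_tracks <- function(vms, ops, vessel_dt = 10) {
  if (!"source" %in% names(vms)) {
    vms <- merge_vms_operations(vms, ops)
  }
  if (!nrow(vms)) {
    return(tibble(
      vessel_id = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      lat = numeric(), lon = numeric(),
      activity = character(), interpolated = logical()
    ))
  }
  step_s <- vessel_dt * 60
  out <- vms |>
    group_by(.data$vessel_id) |>
    group_modify(function(df, key) {
      if (nrow(df) < 2) {
        warn(sprintf("Vessel %s has a single fix; skipped.", key$vessel_id))
        return(tibble(
          timestamp = as.POSIXct(character(), tz = "UTC"),
          lat = numeric(), lon = numeric(), interpolated = logical()
        ))
      }
      tn <- as.numeric(df$timestamp)
      grid0 <- floor(tn[1] / step_s) * step_s
      grid <- seq(grid0 + ceiling((tn[1] - grid0) / step_s) * step_s,
                  max(tn), by = step_s)
      lat_i <- stats::approx(tn, df$lat, grid, ties = "ordered")$y
      lon_i <- stats::approx(tn, df$lon, grid, ties = "ordered")$y
      on_source <- grid %in% tn
      # source fixes on the grid pass through bit-identically
      idx <- match(grid[on_source], tn)
      lat_i[on_source] <- df$lat[idx]
      lon_i[on_source] <- df$lon[idx]
      tibble(
        timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
        lat = lat_i, lon = lon_i, interpolated = !on_source
      )
    }) |>
    ungroup()

  out$activity <- "transit"
  if (nrow(ops)) {
    for (v in unique(out$vessel_id)) {
      ov <- ops[ops$vessel_id == v, ]
      if (!nrow(ov)) next
      sel <- out$vessel_id == v
      tt <- as.numeric(out$timestamp[sel])
      act <- rep("transit", length(tt))
      for (k in seq_len(nrow(ov))) {
        inside <- tt >= as.numeric(ov$t_start[k]) &
          tt < as.numeric(ov$t_end[k])
        act[inside] <- ov$op_type[k]
      }
      out$activity[sel] <- act
    }
  }
  select(out, "vessel_id", "timestamp", "lat", "lon",
         "activity", "interpolated")
}
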