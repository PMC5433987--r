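t0 <- as.POSIXct("2012-01-15 08:00:00", tz = "UTC")

mk_ops <- function(starts_hr, ends_hr, types = "hauling", id = "V01") {
  tibble::tibble(
    vessel_id = id, op_type = rep_len(types, length(starts_hr)),
    t_start = t0 + starts_hr * 3600, t_end = t0 + ends_hr * 3600,
    lat_start = -46.5, lon_start = 52, lat_end = -46.5, lon_end = 52
  )
}

test_that("time to fishing is zero during an operation and the gap otherwise", {
  ops <- mk_ops(c(-2, 5), c(1, 8))
  expect_equal(time_to_fishing(t0, ops), 0) # encounter starts mid-haul
  # operation ended 30 min before the start, next starts 5 hr later
  ops2 <- mk_ops(c(-3, 5), c(-0.5, 8))
  expect_equal(time_to_fishing(t0, ops2), 0.5)
  # or started half an hour after the encounter start
  ops3 <- mk_ops(c(0.5, -8), c(3, -6))
  expect_equal(time_to_fishing(t0, ops3), 0.5)
  # one-sided layouts ignore the unbounded side
  expect_equal(time_to_fishing(t0, mk_ops(2, 4)), 2)
  expect_equal(time_to_fishing(t0, mk_ops(-4, -3)), 3)
  # no operations at all: missing
  expect_true(is.na(time_to_fishing(t0, mk_ops(2, 4)[0, ])))
  # restricted to the event's vessels
  ops4 <- dplyr::bind_rows(mk_ops(1, 2, id = "V01"), mk_ops(4, 5, id = "V02"))
  expect_equal(time_to_fishing(t0, ops4, vessel_ids = "V02"), 4)
  expect_equal(time_to_fishing(t0, ops4, vessel_ids = "V01,V02"), 1)
})

test_that("time to fishing equals an exhaustive scan on random layouts", {
  set.seed(41)
  for (rep in 1:50) {
    k <- sample(1:5, 1)
    edges <- sort(runif(2 * k, -48, 48))
    ops <- mk_ops(edges[seq(1, 2 * k, 2)], edges[seq(2, 2 * k, 2)])
    got <- time_to_fishing(t0, ops)
    # oracle: distance from 0 to the nearest covered hour, by direct check
    inside <- any(edges[seq(1, 2 * k, 2)] <= 0 & 0 < edges[seq(2, 2 * k, 2)])
    if (inside) {
      expect_equal(got, 0)
    } else {
      cand <- c(-edges[seq(2, 2 * k, 2)][edges[seq(2, 2 * k, 2)] <= 0],
                edges[seq(1, 2 * k, 2)][edges[seq(1, 2 * k, 2)] > 0])
      # POSIXct round-trips carry ~1e-7 s of floating error
      expect_equal(got, min(cand), tolerance = 1e-6)
    }
  }
})

test_that("proportion of the event in active fishing counts nearest activity", {
  m <- matched_frame(rep(10, 14))
  m$nearest_activity <- "transit"
  expect_equal(prop_fishing(m), 0)
  m$nearest_activity <- "hauling"
  expect_equal(prop_fishing(m), 1)
  m$nearest_activity <- rep(c("hauling", "transit"), each = 7)
  expect_equal(prop_fishing(m), 0.5)
  expect_error(prop_fishing(m[0, ]), "Empty")
})

test_that("attendance metrics compute duration, proportion and mean distance", {
  d <- c(rep(10, 10), rep(1, 4))
  spd <- c(rep(50, 10), rep(3, 4))
  m <- matched_frame(d, bird_speed = spd)
  am <- attendance_metrics(m, bird_dt = 15)
  expect_equal(am$duration_locs, 4)
  expect_equal(am$duration_hr, 1.0)
  expect_equal(am$prop_of_event, 4 / 14)
  expect_equal(am$mean_distance_m, 1000)
  expect_error(attendance_metrics(matched_frame(rep(50, 3))), "without")
})

test_that("trip summaries count boats, encounters and shelf time correctly", {
  ex <- two_encounter_example()
  p <- analysis_params()
  vt <- interpolate_vessel_tracks(ex$vms, ex$operations)
  m <- match_locations(ex$bird_tracks, vt, p)
  ev <- filter_daylight_flying(segment_encounters(m, p), p)
  ts <- trip_summary(m, ev, vt, ex$bird_meta, p)
  expect_equal(nrow(ts), 1)
  expect_equal(ts$n_encounters, 2)
  expect_true(ts$any_attendance)
  expect_equal(ts$attendance_time_hr, 1.0) # 4 fixes at 15 min
  expect_equal(ts$avg_boats_present, 1) # one stationary vessel, always there
  expect_equal(ts$prop_on_shelf, 1)
  expect_equal(ts$duration_days, 26 * 0.25 / 24)

  # no vessels at all
  vt0 <- vt[0, ]
  m0 <- match_locations(ex$bird_tracks, vt0, p)
  ev0 <- filter_daylight_flying(segment_encounters(m0, p), p)
  ts0 <- trip_summary(m0, ev0, vt0, ex$bird_meta, p)
  expect_equal(ts0$avg_boats_present, 0)
  expect_equal(ts0$n_encounters, 0)
  expect_false(ts0$any_attendance)
})

test_that("a vessel present for half the trip gives average boat count one half", {
  ex <- two_encounter_example()
  p <- analysis_params()
  # truncate the vessel track to cover only the first half of the bird fixes
  n_half <- 14
  cutoff <- ex$bird_tracks$timestamp[n_half]
  vms_half <- ex$vms[ex$vms$timestamp <= cutoff + 600, ]
  vt <- interpolate_vessel_tracks(vms_half, ex$operations)
  m <- match_locations(ex$bird_tracks, vt, p)
  ev <- filter_daylight_flying(segment_encounters(m, p), p)
  ts <- trip_summary(m, ev, vt, ex$bird_meta, p)
  covered <- sum(ex$bird_tracks$timestamp <= max(vt$timestamp) + p$match_tol * 60)
  expect_equal(ts$avg_boats_present, covered / nrow(ex$bird_tracks))
})

test_that("trip totals equal a brute-force recount on simulated data", {
  sc <- tiny_scenario(seed = 42, n_birds = 2)
  p <- analysis_params()
  m <- match_locations(sc$bird_tracks, sc$vessel_tracks, p)
  ev <- filter_daylight_flying(segment_encounters(m, p), p)
  ts <- trip_summary(m, ev, sc$vessel_tracks, sc$bird_meta, p)
  for (tid in ts$trip_id) {
    sl <- m[m$trip_id == tid, ]
    # brute-force per-fix recount of vessels on the shelf
    ref <- mean(vapply(sl$timestamp, function(tt) {
      cnt <- 0
      for (v in unique(sc$vessel_tracks$vessel_id)) {
        tv <- sc$vessel_tracks[sc$vessel_tracks$vessel_id == v, ]
        dt <- abs(as.numeric(tv$timestamp) - as.numeric(tt))
        j <- which.min(dt)
        if (dt[j] <= p$match_tol * 60 &&
            point_in_ring(tv$lon[j], tv$lat[j], p$shelf_polygon)) {
          cnt <- cnt + 1
        }
      }
      cnt
    }, numeric(1)))
    expect_equal(ts$avg_boats_present[ts$trip_id == tid], ref)
    expect_equal(ts$prop_on_shelf[ts$trip_id == tid],
                 mean(point_in_ring(sl$lon, sl$lat, p$shelf_polygon)))
  }
  # attendance time aggregates retained events
  agg <- ev |>
    dplyr::filter(retained_daylight) |>
    dplyr::group_by(trip_id) |>
    dplyr::summarise(hr = sum(n_attendance) * 0.25)
  for (tid in agg$trip_id) {
    expect_equal(ts$attendance_time_hr[ts$trip_id == tid],
                 agg$hr[agg$trip_id == tid])
  }
})

test_that("attendance fix shares by activity class sum to one", {
  sc <- tiny_scenario(seed = 43, n_birds = 3)
  m <- match_locations(sc$bird_tracks, sc$vessel_tracks)
  att <- m[m$is_attendance, ]
  if (nrow(att)) {
    shares <- prop.table(table(factor(
      ifelse(att$nearest_activity %in% c("setting", "hauling"),
             att$nearest_activity, "none"),
      levels = c("hauling", "none", "setting")
    )))
    expect_equal(sum(shares), 1)
  } else {
    succeed("no attendance fixes in this draw")
  }
})
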