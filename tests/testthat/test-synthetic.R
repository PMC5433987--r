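test_that("the generator is reproducible and seed-sensitive", {
  cfg <- scenario_config(n_birds = 2, n_vessels = 1, n_days = 6,
                         trip_duration_range = c(2, 3))
  a <- simulate_scenario(cfg, seed = 7)
  b <- simulate_scenario(cfg, seed = 7)
  expect_identical(a$bird_tracks, b$bird_tracks)
  expect_identical(a$vms, b$vms)
  expect_identical(a$operations, b$operations)
  expect_identical(a$truth, b$truth)
  expect_identical(a$bird_meta, b$bird_meta)
  c <- simulate_scenario(cfg, seed = 8)
  expect_false(identical(a$bird_tracks$lat, c$bird_tracks$lat))
})

test_that("tracks are on exact regular grids and well-formed", {
  sc <- tiny_scenario(seed = 51, n_birds = 2)
  for (tid in unique(sc$bird_tracks$trip_id)) {
    tt <- sc$bird_tracks$timestamp[sc$bird_tracks$trip_id == tid]
    expect_true(all(diff(as.numeric(tt)) == 15 * 60))
  }
  for (vid in unique(sc$vms$vessel_id)) {
    tt <- sc$vms$timestamp[sc$vms$vessel_id == vid]
    expect_true(all(diff(as.numeric(tt)) == 3600))
  }
  expect_true(all(is.finite(sc$bird_tracks$lat)))
  expect_true(all(sc$bird_tracks$lat >= -90 & sc$bird_tracks$lat <= 90))
  expect_true(all(format(sc$bird_tracks$timestamp, "%Z") == "UTC"))
})

test_that("trips start and end at the colony and respect the duration range", {
  sc <- tiny_scenario(seed = 52, n_birds = 3, dur = c(2, 4))
  p <- analysis_params()
  ends <- sc$bird_tracks |>
    dplyr::group_by(trip_id) |>
    dplyr::summarise(
      d0 = dist_haversine_km(dplyr::first(lon), dplyr::first(lat),
                             p$colony$lon, p$colony$lat),
      d1 = dist_haversine_km(dplyr::last(lon), dplyr::last(lat),
                             p$colony$lon, p$colony$lat),
      days = as.numeric(difftime(max(timestamp), min(timestamp),
                                 units = "days"))
    )
  expect_true(all(ends$d0 <= p$colony_radius_km))
  expect_true(all(ends$d1 <= p$colony_radius_km))
  expect_true(all(ends$days >= 1.5)) # configured 2-4 days, allow edge slack
})

test_that("vessels stay inside the shelf polygon and set lines at night", {
  cfg <- scenario_config(n_birds = 1, n_vessels = 2, n_days = 8,
                         trip_duration_range = c(2, 4))
  fleet <- simulate_vessels(cfg, seed = 53)
  p <- analysis_params()
  expect_true(all(point_in_ring(fleet$vms$lon, fleet$vms$lat,
                                p$shelf_polygon)))
  sets <- fleet$operations[fleet$operations$op_type == "setting", ]
  hauls <- fleet$operations[fleet$operations$op_type == "hauling", ]
  expect_gt(nrow(sets), 0)
  expect_gt(nrow(hauls), 0)
  # setting begins in darkness (below civil twilight), hauling in daylight
  elev_set <- solar_elevation(sets$t_start, sets$lon_start, sets$lat_start)
  elev_haul <- solar_elevation(hauls$t_start, hauls$lon_start,
                               hauls$lat_start)
  expect_true(all(elev_set < p$daylight_elev_deg))
  expect_true(all(elev_haul > p$daylight_elev_deg))
  # operations never overlap within a vessel
  for (v in unique(fleet$operations$vessel_id)) {
    ov <- fleet$operations[fleet$operations$vessel_id == v, ]
    ov <- ov[order(ov$t_start), ]
    if (nrow(ov) > 1) {
      expect_true(all(as.numeric(ov$t_start[-1]) >=
                        as.numeric(ov$t_end[-nrow(ov)])))
    }
  }
})

test_that("a fleet of zero vessels yields empty tables and no encounters", {
  cfg <- scenario_config(n_birds = 1, n_vessels = 0, n_days = 5,
                         trip_duration_range = c(2, 3))
  sc <- simulate_scenario(cfg, seed = 54)
  expect_equal(nrow(sc$vms), 0)
  expect_equal(nrow(sc$operations), 0)
  expect_equal(nrow(sc$truth), 0)
  expect_gt(nrow(sc$bird_tracks), 0)
})

test_that("degenerate attendance probabilities are honoured by the truth log", {
  base <- list(n_birds = 3, n_vessels = 2, n_days = 10,
               trip_duration_range = c(2, 4))
  cfg0 <- do.call(scenario_config,
                  c(base, list(p_attend_given_encounter = 0)))
  sc0 <- simulate_scenario(cfg0, seed = 55)
  expect_true(all(!sc0$truth$attended))
  cfg1 <- do.call(scenario_config,
                  c(base, list(p_attend_given_encounter = 1)))
  sc1 <- simulate_scenario(cfg1, seed = 55)
  if (nrow(sc1$truth)) expect_true(all(sc1$truth$attended))
})

test_that("the truth log agrees with the analysis pipeline on the same data", {
  sc <- tiny_scenario(seed = 56, n_birds = 4)
  p <- analysis_params()
  m <- match_locations(sc$bird_tracks, sc$vessel_tracks, p)
  ev <- segment_encounters(m, p)
  tr_ev <- table(ev$trip_id)
  tr_tru <- table(sc$truth$trip_id)
  expect_equal(sum(tr_ev), sum(tr_tru))
  expect_equal(nrow(ev[ev$has_attendance, ]), sum(sc$truth$attended))
  # attended encounters announced in the truth log really show attendance
  # fixes under the standard thresholds
  expect_true(all(ev$n_attendance[ev$has_attendance] > 0))
})

test_that("bird metadata covers both sexes and plausible masses", {
  cfg <- scenario_config(n_birds = 12, n_vessels = 1, n_days = 10,
                         trip_duration_range = c(2, 3))
  sc <- simulate_scenario(cfg, seed = 57)
  expect_setequal(unique(sc$bird_meta$sex), c("M", "F"))
  expect_true(all(sc$bird_meta$mass_departure > 5000))
  expect_true(all(sc$bird_meta$mass_departure < 14000))
  # males are heavier on average, as configured
  mm <- tapply(sc$bird_meta$mass_departure, sc$bird_meta$sex, mean)
  expect_gt(mm["M"], mm["F"])
  expect_true(all(sc$bird_meta$year %in% c(2011, 2012, 2013)))
})

test_that("the worked example is deterministic and matches its design", {
  ex1 <- two_encounter_example()
  ex2 <- two_encounter_example()
  expect_identical(ex1, ex2)
  expect_equal(nrow(ex1$bird_tracks), 27)
  # distances from the stationary vessel reproduce the designed ladder
  d <- dist_haversine_km(ex1$bird_tracks$lon, ex1$bird_tracks$lat, 52, -46.8)
  expect_equal(sum(d < 30), 17) # 3 + 14 in-range fixes
  expect_true(all(
    is_daylight(ex1$bird_tracks$timestamp, ex1$bird_tracks$lon,
                ex1$bird_tracks$lat)
  ))
})
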