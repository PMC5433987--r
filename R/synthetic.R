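#' Configuration for a synthetic bird-vessel scenario
#'
#' Describes a simulated field season: central-place foraging trips sampled
#' at 15-min GPS intervals, and a small longline fleet tracked hourly inside
#' a shelf polygon, with line setting scheduled at night and hauling during
#' the day. Birds are given *programmed* interaction behaviour: on each entry
#' into attraction range they decide to attend with a fixed probability, and
#' an attendance bout keeps them sitting within the attendance radius for a
#' geometrically distributed number of fixes. Every programmed decision is
#' recorded in a ground-truth log so the segmentation and models can be
#' checked against known truth.
#'
#' Defaults mirror the structure of the study system the pipeline is built
#' for: trips of 2-29 days, up to seven vessels, a per-encounter attendance
#' probability near 0.6, bouts of about 4 hr (17 fixes), attendance
#' distances around 1.25 km, and three season labels with most tracks in the
#' low-fleet season. Flight speeds are drawn on 20-80 km/hr and sitting
#' speeds on 0-5 km/hr, both clear of the 10 km/hr classification boundary.
#'
#' @param n_birds Number of birds.
#' @param n_trips_per_bird Trips per bird.
#' @param trip_duration_range Min/max trip duration, days.
#' @param n_vessels Number of vessels (0 to 7).
#' @param n_days Length of the simulated season, days.
#' @param start_date Date (UTC) the season starts.
#' @param shelf_polygon,colony As in [analysis_params()].
#' @param p_attend_given_encounter Probability a bird attends on each entry
#'   into attraction range.
#' @param attend_duration_mean Mean programmed attendance-bout length, fixes.
#' @param attend_distance_scale Mean bird-vessel distance while attending, km.
#' @param foraging_range_km Min/max distance of the trip's far waypoint from
#'   the colony, km.
#' @param p_start_sit Per-fix probability of starting a natural (non-vessel)
#'   sitting bout while commuting.
#' @param sit_bout_mean Mean natural sitting-bout length, fixes.
#' @param sex_ratio Proportion of females.
#' @param age_range Min/max bird age, years.
#' @param years Season labels.
#' @param year_weights Sampling weights for `years` (per bird).
#' @param mass_departure_mean,mass_departure_sd Named vectors (`M`, `F`) of
#'   departure-mass mean and SD, g.
#' @param mass_gain_per_day_mean,mass_gain_per_day_sd Mass-gain model at sea,
#'   g/day.
#' @param attend_mass_effect Additional mass gain (g) per unit of
#'   trip-proportion spent attending; 0 means attendance has no effect.
#' @param bird_dt Bird sampling interval, minutes.
#' @param vms_dt_hr Raw VMS sampling interval, hours.
#' @return An object of class `vb_scenario_config` (a named list).
#' @export
scenario_config <- function(n_birds = 20,
                            n_trips_per_bird = 1,
                            trip_duration_range = c(2, 29),
                            n_vessels = 4,
                            n_days = 45,
                            start_date = "2012-01-10",
                            shelf_polygon = crozet_like_shelf(),
                            colony = list(lon = 51.86, lat = -46.42),
                            p_attend_given_encounter = 0.605,
                            attend_duration_mean = 17,
                            attend_distance_scale = 1.25,
                            foraging_range_km = c(120, 600),
                            p_start_sit = 0.08,
                            sit_bout_mean = 3,
                            sex_ratio = 0.5,
                            age_range = c(7, 45),
                            years = c("2011", "2012", "2013"),
                            year_weights = c(0.22, 0.12, 0.66),
                            mass_departure_mean = c(M = 10300, F = 8600),
                            mass_departure_sd = c(M = 550, F = 450),
                            mass_gain_per_day_mean = 25,
                            mass_gain_per_day_sd = 12,
                            attend_mass_effect = 0,
                            bird_dt = 15,
                            vms_dt_hr = 1) {
  stopifnot(
    n_birds >= 1, n_trips_per_bird >= 1,
    length(trip_duration_range) == 2, all(trip_duration_range > 0),
    n_vessels >= 0, n_vessels <= 7,
    p_attend_given_encounter >= 0, p_attend_given_encounter <= 1,
    attend_duration_mean >= 1, attend_distance_scale > 0,
    sex_ratio >= 0, sex_ratio <= 1,
    p_start_sit >= 0, p_start_sit <= 1
  )
  if (max(trip_duration_range) > n_days) {
    abort("`n_days` must cover the longest possible trip.")
  }
  structure(
    as.list(environment()),
    class = "vb_scenario_config"
  )
}

season_start <- function(cfg) {
  as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
}

# uniform point inside the polygon's bounding box, rejection-sampled into it
rpoint_in_ring <- function(ring) {
  for (i in 1:200) {
    lon <- runif(1, min(ring$lon), max(ring$lon))
    lat <- runif(1, min(ring$lat), max(ring$lat))
    if (point_in_ring(lon, lat, ring)) return(c(lon = lon, lat = lat))
  }
  abort("Could not sample a point inside the polygon.")
}

#' Simulate the fishing fleet
#'
#' Each vessel performs a correlated random walk constrained to the shelf
#' polygon, recorded hourly (raw VMS). Each day it runs one line-setting
#' operation starting at night (solar elevation below -6 degrees at the
#' start position) and one hauling operation during the day; vessels move
#' slowly while operating. Operation start/end positions are taken on the
#' vessel's path.
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer seed for this stage.
#' @return A list with `vms` (tibble: vessel_id, timestamp, lat, lon) and
#'   `operations` (tibble in the standard operations dialect).
#' @export
simulate_vessels <- function(cfg, seed = 1) {
  empty_ops <- tibble(
    vessel_id = character(), op_type = character(),
    t_start = as.POSIXct(character(), tz = "UTC"),
    t_end = as.POSIXct(character(), tz = "UTC"),
    lat_start = numeric(), lon_start = numeric(),
    lat_end = numeric(), lon_end = numeric()
  )
  if (cfg$n_vessels == 0) {
    return(list(
      vms = tibble(vessel_id = character(),
                   timestamp = as.POSIXct(character(), tz = "UTC"),
                   lat = numeric(), lon = numeric()),
      operations = empty_ops
    ))
  }
  set.seed(seed + 1000L)
  t0 <- season_start(cfg)
  hours <- seq(0, cfg$n_days * 24, by = cfg$vms_dt_hr)
  times <- t0 + hours * 3600
  n <- length(times)
  ring <- cfg$shelf_polygon

  vms <- vector("list", cfg$n_vessels)
  ops <- vector("list", cfg$n_vessels)
  for (v in seq_len(cfg$n_vessels)) {
    vid <- sprintf("V%02d", v)
    # daily operation windows, anchored on local solar noon/midnight
    op_v <- list()
    for (d in seq_len(cfg$n_days) - 1) {
      day0 <- t0 + d * 86400
      probe <- day0 + seq(0, 23) * 3600
      # elevation probed at the polygon centroid; vessels stay inside it
      elev <- solar_elevation(probe, mean(ring$lon), mean(ring$lat))
      t_noon <- probe[which.max(elev)]
      t_midn <- probe[which.min(elev)]
      haul_start <- t_noon - runif(1, 1.5, 2.5) * 3600
      haul_end <- haul_start + runif(1, 4, 7) * 3600
      set_start <- t_midn - runif(1, 0, 1.25) * 3600
      set_end <- set_start + runif(1, 2, 3.5) * 3600
      op_v[[length(op_v) + 1]] <- tibble(
        vessel_id = vid,
        op_type = c("hauling", "setting"),
        t_start = c(haul_start, set_start),
        t_end = c(haul_end, set_end)
      )
    }
    op_v <- arrange(bind_rows(op_v), .data$t_start)
    # guard: drop any op starting before the previous one ends
    keep <- c(TRUE, op_v$t_start[-1] > op_v$t_end[-nrow(op_v)])
    op_v <- op_v[keep, ]

    in_op <- function(tt) {
      any(op_v$t_start <= tt & tt < op_v$t_end)
    }

    lon <- numeric(n)
    lat <- numeric(n)
    p <- rpoint_in_ring(ring)
    lon[1] <- p[["lon"]]
    lat[1] <- p[["lat"]]
    heading <- runif(1, 0, 360)
    for (i in 2:n) {
      speed <- if (in_op(times[i - 1])) runif(1, 2, 5) else runif(1, 8, 14)
      step <- speed * cfg$vms_dt_hr
      ok <- FALSE
      h <- heading + rnorm(1, 0, 35)
      for (try in 1:25) {
        cand <- move_point(lon[i - 1], lat[i - 1], h, step)
        if (point_in_ring(cand$lon, cand$lat, ring)) {
          ok <- TRUE
          break
        }
        h <- runif(1, 0, 360)
      }
      if (!ok) cand <- list(lon = lon[i - 1], lat = lat[i - 1])
      lon[i] <- cand$lon
      lat[i] <- cand$lat
      heading <- h
    }

    # operation endpoint positions: on-path, by linear interpolation in time
    tnum <- as.numeric(times)
    interp_pos <- function(tt) {
      ttn <- as.numeric(tt)
      list(lon = stats::approx(tnum, lon, ttn, rule = 2)$y,
           lat = stats::approx(tnum, lat, ttn, rule = 2)$y)
    }
    ps <- interp_pos(op_v$t_start)
    pe <- interp_pos(op_v$t_end)
    op_v$lon_start <- ps$lon
    op_v$lat_start <- ps$lat
    op_v$lon_end <- pe$lon
    op_v$lat_end <- pe$lat

    # contract: setting starts at night; nudge a violating start to the
    # darkest probed instant of its day
    is_set <- op_v$op_type == "setting"
    if (any(is_set)) {
      el <- solar_elevation(op_v$t_start[is_set], op_v$lon_start[is_set],
                            op_v$lat_start[is_set])
      bad <- which(el >= -6)
      for (b in bad) {
        idx <- which(is_set)[b]
        day0 <- as.POSIXct(trunc(op_v$t_start[idx], "days"), tz = "UTC")
        probe <- day0 + seq(0, 1439, by = 10) * 60
        elp <- solar_elevation(probe, op_v$lon_start[idx], op_v$lat_start[idx])
        shift <- probe[which.min(elp)] - op_v$t_start[idx]
        op_v$t_start[idx] <- op_v$t_start[idx] + shift
        op_v$t_end[idx] <- op_v$t_end[idx] + shift
      }
    }

    vms[[v]] <- tibble(vessel_id = vid, timestamp = times, lat = lat, lon = lon)
    ops[[v]] <- op_v
  }
  ops <- bind_rows(ops) |>
    select("vessel_id", "op_type", "t_start", "t_end",
           "lat_start", "lon_start", "lat_end", "lon_end")
  list(vms = bind_rows(vms), operations = ops)
}

# fast nearest-in-time lookup tables for interpolated vessel tracks
vessel_lookup <- function(vessel_tracks) {
  split(vessel_tracks, vessel_tracks$vessel_id) |>
    lapply(function(tr) {
      tr <- arrange(tr, .data$timestamp)
      list(t = as.numeric(tr$timestamp), lon = tr$lon, lat = tr$lat,
           activity = tr$activity)
    })
}

# nearest vessel point within tol_s of time tt; NULL when out of span
nearest_vessel_point <- function(lk, tt, tol_s) {
  i <- findInterval(tt, lk$t)
  cand <- unique(pmin(pmax(c(i, i + 1), 1), length(lk$t)))
  dt <- abs(lk$t[cand] - tt)
  j <- cand[which.min(dt)]
  if (min(dt) > tol_s) return(NULL)
  list(lon = lk$lon[j], lat = lk$lat[j], activity = lk$activity[j])
}

#' Simulate bird foraging trips with programmed vessel interactions
#'
#' Each trip is a biased correlated random walk leaving the colony toward a
#' far waypoint and returning, sampled every `bird_dt` minutes, with flight
#' speeds of 20-80 km/hr interleaved with natural sitting bouts below
#' 5 km/hr. Whenever the bird enters attraction range of any vessel (after
#' having been out of range for more than the time-to-return allowance), a
#' Bernoulli draw with probability `p_attend_given_encounter` decides whether
#' it attends: if yes it flies to the vessel, sits within the attendance
#' radius for a geometric number of fixes and then departs; if no it keeps
#' flying until it has left the range. Every such entry is recorded in the
#' returned ground-truth log.
#'
#' @param cfg A [scenario_config()].
#' @param vessel_tracks Interpolated vessel tracks
#'   (see [interpolate_vessel_tracks()]); may have zero rows.
#' @param params An [analysis_params()]; supplies the attraction/attendance
#'   radii and the time-to-return allowance the programmed behaviour uses.
#' @param seed Integer seed for this stage.
#' @return A list with `bird_tracks`, `bird_meta`, and `truth` (one row per
#'   programmed range entry: bird_id, trip_id, t_entry, vessel_id, attended,
#'   bout_locs).
#' @export
simulate_birds <- function(cfg, vessel_tracks, params = analysis_params(),
                           seed = 1) {
  set.seed(seed + 2000L)
  t0 <- season_start(cfg)
  dt_s <- cfg$bird_dt * 60
  dt_hr <- cfg$bird_dt / 60
  lk <- if (nrow(vessel_tracks)) vessel_lookup(vessel_tracks) else list()
  tol_s <- params$match_tol * 60

  tracks <- list()
  truth <- list()

  meta <- tibble(
    bird_id = sprintf("B%03d", seq_len(cfg$n_birds)),
    sex = ifelse(runif(cfg$n_birds) < cfg$sex_ratio, "F", "M"),
    age = sample(seq(cfg$age_range[1], cfg$age_range[2]),
                 cfg$n_birds, replace = TRUE),
    year = sample(cfg$years, cfg$n_birds, replace = TRUE,
                  prob = cfg$year_weights)
  )

  for (b in seq_len(cfg$n_birds)) {
    for (tr in seq_len(cfg$n_trips_per_bird)) {
      trip_id <- sprintf("%s_T%d", meta$bird_id[b], tr)
      dur_days <- runif(1, cfg$trip_duration_range[1],
                        cfg$trip_duration_range[2])
      n_fix <- max(8L, as.integer(round(dur_days * 24 / dt_hr)))
      # allow some overrun so delayed birds still make it back to the colony
      n_alloc <- as.integer(ceiling(n_fix * 1.5))
      start_slack <- max(0, cfg$n_days - dur_days - 0.5)
      t_start <- t0 + round(runif(1, 0, start_slack * 96)) * dt_s
      times <- t_start + (seq_len(n_alloc) - 1) * dt_s

      wp_bearing <- runif(1, 0, 360)
      wp_dist <- runif(1, cfg$foraging_range_km[1], cfg$foraging_range_km[2])
      wp <- move_point(cfg$colony$lon, cfg$colony$lat, wp_bearing, wp_dist)

      lon <- numeric(n_alloc)
      lat <- numeric(n_alloc)
      lon[1] <- cfg$colony$lon
      lat[1] <- cfg$colony$lat

      mode <- "out"           # out | return | approach | attend | depart
      sit_left <- 0L          # remaining natural sitting fixes
      avoid_left <- 0L        # forced-flying fixes after leaving a vessel
      out_streak <- Inf       # consecutive out-of-range fixes so far
      attend_left <- 0L
      attend_vid <- NA_character_
      forced_fly <- FALSE     # non-attending pass through range
      last_i <- n_alloc

      for (i in 2:n_alloc) {
        tt <- as.numeric(times[i])
        prev_lon <- lon[i - 1]
        prev_lat <- lat[i - 1]

        if (mode == "attend") {
          vp <- nearest_vessel_point(lk[[attend_vid]], tt, tol_s)
          placed <- FALSE
          if (!is.null(vp)) {
            off_d <- min(rexp(1, 1 / cfg$attend_distance_scale) + 0.2,
                         0.9 * params$attendance_km)
            cand <- move_point(vp$lon, vp$lat, runif(1, 0, 360), off_d)
            step <- dist_haversine_km(prev_lon, prev_lat, cand$lon, cand$lat,
                                      params$earth_radius_km)
            if (step / dt_hr < 0.9 * params$sit_speed_kmh) {
              lon[i] <- cand$lon
              lat[i] <- cand$lat
              placed <- TRUE
            }
          }
          if (!placed) {
            # vessel moved too fast (or left span): bout ends here
            mode <- "depart"
            avoid_left <- as.integer(2 * params$time_to_return_locs + 6)
            lon[i] <- prev_lon
            lat[i] <- prev_lat
          } else {
            attend_left <- attend_left - 1L
            if (attend_left <= 0L) {
              mode <- "depart"
              avoid_left <- as.integer(2 * params$time_to_return_locs + 6)
            }
          }
        } else if (mode == "approach") {
          vp <- nearest_vessel_point(lk[[attend_vid]], tt, tol_s)
          if (is.null(vp)) {
            mode <- "depart"
            avoid_left <- as.integer(params$time_to_return_locs + 4)
            lon[i] <- prev_lon
            lat[i] <- prev_lat
          } else {
            d <- dist_haversine_km(prev_lon, prev_lat, vp$lon, vp$lat,
                                   params$earth_radius_km)
            spd <- runif(1, 40, 80)
            if (d <= spd * dt_hr) {
              # arrive: anticipate the vessel's next-grid position so the
              # following fix is a genuine sitting fix beside the boat
              vnext <- nearest_vessel_point(lk[[attend_vid]], tt + dt_s, tol_s)
              anchor <- if (is.null(vnext)) vp else vnext
              off_d <- min(rexp(1, 1 / cfg$attend_distance_scale) + 0.2,
                           0.8 * params$attendance_km)
              cand <- move_point(anchor$lon, anchor$lat,
                                 runif(1, 0, 360), off_d)
              lon[i] <- cand$lon
              lat[i] <- cand$lat
              mode <- "attend"
            } else {
              brg <- bearing_deg(prev_lon, prev_lat, vp$lon, vp$lat)
              cand <- move_point(prev_lon, prev_lat, brg + rnorm(1, 0, 5),
                                 spd * dt_hr)
              lon[i] <- cand$lon
              lat[i] <- cand$lat
            }
          }
        } else {
          # commuting (out / return / depart)
          target <- if (mode == "return") cfg$colony else wp
          if (mode == "depart") {
            # head away from the attended vessel's last known point
            brg <- bearing_deg(lon[i - 1], lat[i - 1], target$lon, target$lat)
          } else {
            brg <- bearing_deg(prev_lon, prev_lat, target$lon, target$lat)
          }
          sitting <- FALSE
          if (sit_left > 0L) {
            sitting <- TRUE
            sit_left <- sit_left - 1L
          } else if (!forced_fly && avoid_left == 0L &&
                     runif(1) < cfg$p_start_sit) {
            sitting <- TRUE
            sit_left <- rgeom(1, 1 / cfg$sit_bout_mean)
          }
          spd <- if (sitting) runif(1, 0, 5) else runif(1, 20, 80)
          noise <- if (sitting) runif(1, 0, 360) else rnorm(1, 0, 25)
          hdg <- if (sitting) noise else brg + noise
          cand <- move_point(prev_lon, prev_lat, hdg, spd * dt_hr)
          lon[i] <- cand$lon
          lat[i] <- cand$lat
          if (avoid_left > 0L) avoid_left <- avoid_left - 1L
        }

        # range bookkeeping against every vessel
        in_range <- FALSE
        nearest_d <- Inf
        nearest_v <- NA_character_
        for (vid in names(lk)) {
          vp <- nearest_vessel_point(lk[[vid]], tt, tol_s)
          if (is.null(vp)) next
          d <- dist_haversine_km(lon[i], lat[i], vp$lon, vp$lat,
                                 params$earth_radius_km)
          if (d < nearest_d) {
            nearest_d <- d
            nearest_v <- vid
          }
        }
        in_range <- nearest_d < params$attraction_km

        if (in_range) {
          new_entry <- out_streak > params$time_to_return_locs
          if (new_entry && mode %in% c("out", "return", "depart")) {
            mode <- if (mode == "depart") "out" else mode
            avoid_left <- 0L
            attended <- runif(1) < cfg$p_attend_given_encounter
            bout <- 0L
            if (attended) {
              bout <- rgeom(1, 1 / cfg$attend_duration_mean) + 1L
              mode <- "approach"
              attend_vid <- nearest_v
              attend_left <- bout
              forced_fly <- FALSE
            } else {
              forced_fly <- TRUE
            }
            truth[[length(truth) + 1]] <- tibble(
              bird_id = meta$bird_id[b], trip_id = trip_id,
              t_entry = times[i], vessel_id = nearest_v,
              attended = attended, bout_locs = bout
            )
          }
          out_streak <- 0
        } else {
          out_streak <- out_streak + 1
          if (forced_fly && out_streak > params$time_to_return_locs) {
            forced_fly <- FALSE
          }
          if (mode == "depart" && avoid_left == 0L) {
            mode <- if (i > n_fix * 0.55) "return" else "out"
          }
        }

        # phase switching and homing: wander between waypoints until the
        # remaining time budget is just enough to fly home
        if (mode == "out") {
          d_wp <- dist_haversine_km(lon[i], lat[i], wp$lon, wp$lat,
                                    params$earth_radius_km)
          if (d_wp < 20) {
            wp <- move_point(lon[i], lat[i], runif(1, 0, 360),
                             runif(1, 80, 400))
          }
          d_col <- dist_haversine_km(lon[i], lat[i], cfg$colony$lon,
                                     cfg$colony$lat, params$earth_radius_km)
          fixes_home <- d_col / (40 * dt_hr)
          if (n_fix - i <= 1.4 * fixes_home + 4) mode <- "return"
        }
        if (mode == "return") {
          d_col <- dist_haversine_km(lon[i], lat[i], cfg$colony$lon,
                                     cfg$colony$lat, params$earth_radius_km)
          if (d_col < 15) {
            lon[i] <- cfg$colony$lon
            lat[i] <- cfg$colony$lat
            last_i <- i
            break
          }
        }
      }

      tracks[[length(tracks) + 1]] <- tibble(
        bird_id = meta$bird_id[b],
        trip_id = trip_id,
        timestamp = times[seq_len(last_i)],
        lat = lat[seq_len(last_i)],
        lon = lon[seq_len(last_i)]
      )
    }
  }

  truth <- if (length(truth)) bind_rows(truth) else tibble(
    bird_id = character(), trip_id = character(),
    t_entry = as.POSIXct(character(), tz = "UTC"),
    vessel_id = character(), attended = logical(), bout_locs = integer()
  )
  list(bird_tracks = bind_rows(tracks), bird_meta = meta, truth = truth)
}

bearing_deg <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlon <- (lon2 - lon1) * to_rad
  y <- sin(dlon) * cos(lat2 * to_rad)
  x <- cos(lat1 * to_rad) * sin(lat2 * to_rad) -
    sin(lat1 * to_rad) * cos(lat2 * to_rad) * cos(dlon)
  (atan2(y, x) / to_rad) %% 360
}

#' Simulate a complete scenario
#'
#' Runs [simulate_vessels()], interpolates the fleet to the vessel grid, runs
#' [simulate_birds()] against it, and attaches bird masses. Sub-stages use
#' fixed offsets from `seed`, so e.g. the vessel fleet is reproducible
#' independently of the bird settings.
#'
#' @param cfg A [scenario_config()].
#' @param params An [analysis_params()].
#' @param seed Integer master seed.
#' @return A list with `bird_tracks`, `bird_meta` (including masses), `vms`,
#'   `operations`, `vessel_tracks` (interpolated), and `truth`.
#' @export
simulate_scenario <- function(cfg = scenario_config(),
                              params = analysis_params(),
                              seed = 1) {
  fleet <- simulate_vessels(cfg, seed = seed)
  vt <- interpolate_vessel_tracks(fleet$vms, fleet$operations,
                                  vessel_dt = params$vessel_dt)
  birds <- simulate_birds(cfg, vt, params = params, seed = seed)

  set.seed(seed + 3000L)
  meta <- birds$bird_meta
  # masses from the bird's first trip; attendance effect defaults to zero
  first_trips <- birds$bird_tracks |>
    group_by(.data$bird_id, .data$trip_id) |>
    summarise(
      t0 = min(.data$timestamp), t1 = max(.data$timestamp), .groups = "drop"
    ) |>
    group_by(.data$bird_id) |>
    slice_min(.data$t0, n = 1, with_ties = FALSE) |>
    ungroup() |>
    mutate(days = as.numeric(difftime(.data$t1, .data$t0, units = "days")))
  att_prop <- birds$truth |>
    group_by(.data$bird_id) |>
    summarise(att_locs = sum(.data$bout_locs), .groups = "drop")
  meta <- meta |>
    left_join(select(first_trips, "bird_id", "days"), by = "bird_id") |>
    left_join(att_prop, by = "bird_id") |>
    mutate(
      att_locs = ifelse(is.na(.data$att_locs), 0, .data$att_locs),
      att_prop = .data$att_locs * cfg$bird_dt / 60 /
        pmax(.data$days * 24, 1e-9),
      mass_departure = rnorm(
        n(), cfg$mass_departure_mean[.data$sex],
        cfg$mass_departure_sd[.data$sex]
      ),
      mass_return = .data$mass_departure +
        .data$days * rnorm(n(), cfg$mass_gain_per_day_mean,
                           cfg$mass_gain_per_day_sd) +
        cfg$attend_mass_effect * .data$att_prop
    ) |>
    select("bird_id", "sex", "age", "year", "mass_departure", "mass_return")

  list(
    bird_tracks = birds$bird_tracks,
    bird_meta = meta,
    vms = fleet$vms,
    operations = fleet$operations,
    vessel_tracks = vt,
    truth = birds$truth
  )
}

#' Deterministic two-encounter worked example
#'
#' Builds, with no randomness, one bird track and one stationary vessel that
#' realise the canonical two-event schematic used throughout the
#' documentation: a first encounter of 3 consecutive in-range locations with
#' no attendance, a lag of 6 out-of-range locations (longer than the 4-fix
#' time-to-return allowance, so the encounters stay distinct), and a second
#' encounter of 14 in-range locations of which exactly 4 are attendance
#' locations (within 3 km, speed below 10 km/hr). All fixes fall in daylight
#' and both events contain flying fixes, so the daylight-flying filter
#' retains both. Attendance covers 4/14 of the second event, which prints as
#' 29% after rounding.
#'
#' The bird travels along the meridian through the vessel so bird-vessel
#' distances equal the designed values exactly; the schematic is about the
#' segmentation rules and is not anchored at a colony.
#'
#' @param date UTC date of the example (kept in austral summer so the window
#'   is daylight at 46 S).
#' @return A list with `bird_tracks`, `bird_meta`, `vms` (hourly, stationary
#'   vessel), and an empty `operations` table, in the standard dialects.
#' @export
two_encounter_example <- function(date = "2012-01-15") {
  v_lon <- 52.0
  v_lat <- -46.8
  # bird-vessel distance (km) at each 15-min fix; in-range means < 30 km
  d <- c(
    40, 34,                                    # approach, out of range
    28, 24, 27,                                # encounter 1: 3 locations
    33, 38, 45, 50, 45, 38,                    # 6-location lag out of range
    28, 23, 18, 13, 8, 4,                      # encounter 2 begins, flying
    2.2, 1.6, 1.2, 1.5,                        # 4 attendance locations
    5, 11, 18, 25,                             # still in range, flying
    33, 41                                     # departure, out of range
  )
  t0 <- as.POSIXct(paste(date, "06:00:00"), tz = "UTC")
  times <- t0 + (seq_along(d) - 1) * 900
  km_per_deg <- pi * 6371 / 180
  bird <- tibble(
    bird_id = "demo_bird",
    trip_id = "demo_trip",
    timestamp = times,
    lat = v_lat + d / km_per_deg,
    lon = v_lon
  )
  vms_times <- seq(t0 - 3600, t0 + 8 * 3600, by = 3600)
  vms <- tibble(
    vessel_id = "demo_vessel",
    timestamp = vms_times,
    lat = v_lat,
    lon = v_lon
  )
  list(
    bird_tracks = bird,
    bird_meta = tibble(bird_id = "demo_bird", sex = "F", age = 12L,
                       year = "2012", mass_departure = NA_real_,
                       mass_return = NA_real_),
    vms = vms,
    operations = tibble(
      vessel_id = character(), op_type = character(),
      t_start = as.POSIXct(character(), tz = "UTC"),
      t_end = as.POSIXct(character(), tz = "UTC"),
      lat_start = numeric(), lon_start = numeric(),
      lat_end = numeric(), lon_end = numeric()
    )
  )
}
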