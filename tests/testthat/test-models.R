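# Small deterministic trip/event frames for design building
mk_trips <- function(n = 12) {
  tibble::tibble(
    bird_id = paste0("B", rep(1:(n / 2), each = 2)),
    trip_id = paste0("T", 1:n),
    n_encounters = rep(0:2, length.out = n),
    duration_days = seq(2, 8, length.out = n),
    avg_boats_present = runif(n),
    sex = rep(c("M", "F"), length.out = n),
    age = rep(c(8, 15, 25), length.out = n),
    year = rep(c(2011, 2012, 2013), length.out = n)
  )
}

mk_events <- function(n = 16) {
  tibble::tibble(
    bird_id = paste0("B", rep(1:4, length.out = n)),
    trip_id = paste0("T", rep(1:8, length.out = n)),
    has_attendance = rep(c(TRUE, FALSE), length.out = n),
    retained_daylight = rep(c(TRUE, TRUE, TRUE, FALSE), length.out = n),
    n_attendance = rep(c(4L, 0L), length.out = n),
    n_locations = rep(10L, n),
    mean_distance_m = runif(n, 200, 2500),
    time_to_fishing = c(NA, runif(n - 1, 0, 12)),
    prop_fishing = runif(n),
    avg_boats_in_range = runif(n, 1, 2),
    sex = rep(c("M", "F"), length.out = n),
    age = rep(c(8, 15), length.out = n),
    year = rep(c(2011, 2013), length.out = n),
    year_group = rep(c("2011-12", "2013"), length.out = n)
  )
}

test_that("design frames select the right rows and coerce factors", {
  set.seed(61)
  trips <- mk_trips()
  d1 <- build_design("encounter_rate", trips = trips)
  expect_setequal(
    names(d1),
    c("n_encounters", "age", "sex", "avg_boats_present", "duration_days",
      "bird_id", "trip_id")
  )
  expect_s3_class(d1$sex, "factor")
  expect_equal(nrow(d1), nrow(trips))

  ev <- mk_events()
  # only retained events; the row with missing time_to_fishing is dropped
  expect_message(
    d2 <- build_design("attend_prob", events = ev),
    "1 row"
  )
  expect_equal(nrow(d2), sum(ev$retained_daylight) - 1)
  expect_true(all(d2$has_attendance %in% 0:1))

  # attended-only models restrict further
  d3 <- build_design("attend_duration", events = ev)
  expect_equal(nrow(d3), sum(ev$retained_daylight & ev$has_attendance))
})

test_that("alpha one keeps every interaction; near-zero alpha prunes them all", {
  set.seed(62)
  n <- 120
  d <- tibble::tibble(
    bird_id = factor(rep(1:20, each = 6)),
    x = rnorm(n), g = factor(rep(c("a", "b"), n / 2)),
    y = rnorm(n)
  )
  spec <- list(name = "toy", response = "y", family = "gaussian",
               offset = NULL, fixed = c("x", "g", "x:g"),
               random = "(1 | bird_id)", level = "trip")
  keep <- fit_with_pruning(spec, d, alpha = 1)
  expect_equal(nrow(keep$pruned), 0)
  expect_true("x:g" %in% attr(stats::terms(keep$formula), "term.labels"))
  drop <- fit_with_pruning(spec, d, alpha = 1e-12)
  expect_equal(drop$pruned$term, "x:g")
  expect_false("x:g" %in% attr(stats::terms(drop$formula), "term.labels"))
  # main effects are never pruned
  expect_true(all(c("x", "g") %in%
                    attr(stats::terms(drop$formula), "term.labels")))
})

test_that("a strong simulated interaction survives pruning, a null one does not", {
  set.seed(63)
  n <- 400
  d <- tibble::tibble(
    bird_id = factor(rep(1:40, each = 10)),
    x = rnorm(n),
    g = factor(rep(c("a", "b"), each = n / 2))
  )
  spec <- list(name = "toy", response = "y", family = "gaussian",
               offset = NULL, fixed = c("x", "g", "x:g"),
               random = "(1 | bird_id)", level = "trip")
  d$y <- 1 + 0.5 * d$x + (d$g == "b") * 2 * d$x + rnorm(n, sd = 0.5)
  strong <- fit_with_pruning(spec, d, alpha = 0.05)
  expect_equal(nrow(strong$pruned), 0)
  d$y <- 1 + 0.5 * d$x + rnorm(n, sd = 0.5)
  null <- fit_with_pruning(spec, d, alpha = 0.05)
  expect_equal(null$pruned$term, "x:g")
})

test_that("pruning is invariant to row order", {
  set.seed(64)
  n <- 200
  d <- tibble::tibble(
    bird_id = factor(rep(1:20, each = 10)),
    x = rnorm(n), z = rnorm(n),
    g = factor(rep(c("a", "b"), n / 2))
  )
  d$y <- rbinom(n, 1, plogis(0.3 * d$x))
  spec <- list(name = "toy", response = "y", family = "binomial",
               offset = NULL, fixed = c("x", "z", "g", "x:g", "z:g"),
               random = "(1 | bird_id)", level = "trip")
  f1 <- fit_with_pruning(spec, d, alpha = 0.05)
  f2 <- fit_with_pruning(spec, d[sample(n), ], alpha = 0.05)
  expect_setequal(f1$pruned$term, f2$pruned$term)
  expect_equal(sort(attr(stats::terms(f1$formula), "term.labels")),
               sort(attr(stats::terms(f2$formula), "term.labels")))
})

test_that("the binomial engine recovers a known slope within three SEs", {
  set.seed(65)
  n <- 2000
  d <- tibble::tibble(
    bird_id = factor(rep(1:100, each = 20)),
    x = rnorm(n)
  )
  b_re <- rnorm(100, sd = 0.5)[as.integer(d$bird_id)]
  d$y <- rbinom(n, 1, plogis(-0.5 + 1.2 * d$x + b_re))
  spec <- list(name = "toy", response = "y", family = "binomial",
               offset = NULL, fixed = "x",
               random = "(1 | bird_id)", level = "trip")
  fit <- fit_with_pruning(spec, d)
  expect_true(fit$converged)
  expect_true(fit$mixed)
  td <- tidy(fit)
  est <- td$estimate[td$term == "x"]
  se <- td$std.error[td$term == "x"]
  expect_lt(abs(est - 1.2), 3 * se)
})

test_that("the negative-binomial engine is consistent on Poisson-like counts", {
  set.seed(66)
  n <- 1000
  d <- tibble::tibble(
    bird_id = factor(rep(1:50, each = 20)),
    x = rnorm(n), expo = runif(n, 1, 3)
  )
  d$y <- rpois(n, exp(0.2 + 0.7 * d$x + log(d$expo)))
  spec <- list(name = "toy", response = "y", family = "nbinom2",
               offset = "log(expo)", fixed = "x",
               random = "(1 | bird_id)", level = "trip")
  fit <- fit_with_pruning(spec, d)
  td <- tidy(fit)
  est <- td$estimate[td$term == "x"]
  se <- td$std.error[td$term == "x"]
  expect_lt(abs(est - 0.7), 3 * se)
  # equi-dispersed data: the nbinom2 dispersion parameter is very large
  expect_gt(glmmTMB::sigma(fit$fit), 20)
})

mk_mass_meta <- function(n, gain_slope = 0, seed = 1) {
  set.seed(seed)
  sex <- rep(c("M", "F"), length.out = n)
  dep <- ifelse(sex == "M", 10300, 8600) + rnorm(n, sd = 400)
  att <- runif(n, 0, 0.2)
  tibble::tibble(
    bird_id = paste0("B", 1:n), sex = sex,
    age = sample(8:30, n, TRUE), year = rep(c(2012, 2013), length.out = n),
    mass_departure = dep,
    mass_return = dep + 150 + gain_slope * att + rnorm(n, sd = 30),
    .att = att
  )
}

mk_mass_trips <- function(meta) {
  tibble::tibble(
    bird_id = meta$bird_id, trip_id = paste0("T", seq_len(nrow(meta))),
    attendance_prop_of_trip = meta$.att
  )
}

test_that("the mass-gain model centres departure mass within sex", {
  meta <- mk_mass_meta(24, seed = 67)
  fit <- fit_mass_gain(dplyr::select(meta, -".att"), mk_mass_trips(meta))
  an <- tapply(fit$data$departure_anomaly, fit$data$sex, mean)
  expect_true(all(abs(an) < 1e-9))
  expect_s3_class(fit$fit, "lm")
  expect_false(fit$mixed)
})

test_that("the mass-gain model recovers attendance effects of either sign", {
  meta0 <- mk_mass_meta(60, gain_slope = 0, seed = 68)
  f0 <- fit_mass_gain(dplyr::select(meta0, -".att"), mk_mass_trips(meta0))
  td0 <- tidy(f0)
  r0 <- td0[td0$term == "attendance_prop", ]
  expect_gt(r0$p.value, 0.001) # no effect simulated
  expect_lt(abs(r0$estimate), 3 * r0$std.error)

  meta1 <- mk_mass_meta(60, gain_slope = -800, seed = 69)
  f1 <- fit_mass_gain(dplyr::select(meta1, -".att"), mk_mass_trips(meta1))
  td1 <- tidy(f1)
  r1 <- td1[td1$term == "attendance_prop", ]
  expect_lt(r1$estimate, 0)
  expect_lt(abs(r1$estimate - (-800)), 3 * r1$std.error)
})

test_that("nest-mass-loss correction shifts the gain by the declared rate", {
  meta <- mk_mass_meta(20, seed = 70)
  meta$days_on_nest_pre <- 2
  meta$days_on_nest_post <- 1
  p0 <- analysis_params()
  p1 <- analysis_params(nest_mass_loss_rate = 80)
  f0 <- fit_mass_gain(dplyr::select(meta, -".att"), mk_mass_trips(meta), p0)
  f1 <- fit_mass_gain(dplyr::select(meta, -".att"), mk_mass_trips(meta), p1)
  # gain = (return + 80*1) - (departure - 80*2): +240 g per bird
  expect_equal(f1$data$mass_gain, f0$data$mass_gain + 240)
})

test_that("mass-gain input contracts are enforced", {
  meta <- mk_mass_meta(10, seed = 71)
  dup <- dplyr::bind_rows(meta, meta[1, ])
  expect_error(
    fit_mass_gain(dplyr::select(dup, -".att"), mk_mass_trips(dup)),
    "One record per bird"
  )
  one_sex <- dplyr::mutate(meta, sex = "M")
  expect_error(
    fit_mass_gain(dplyr::select(one_sex, -".att"), mk_mass_trips(one_sex)),
    "each sex"
  )
})

test_that("tidy and glance return the documented shapes", {
  set.seed(72)
  n <- 100
  d <- tibble::tibble(
    bird_id = factor(rep(1:10, each = 10)),
    x = rnorm(n), y = rnorm(n)
  )
  spec <- list(name = "toy", response = "y", family = "gaussian",
               offset = NULL, fixed = "x",
               random = "(1 | bird_id)", level = "trip")
  fit <- fit_with_pruning(spec, d)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_true("(Intercept)" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$nobs, n)
  expect_equal(gl$n_birds, 10)
  expect_true(is.finite(gl$AIC))
  expect_output(print(fit), "toy")
})

test_that("model results serialise to readable text artefacts", {
  meta <- mk_mass_meta(20, seed = 73)
  fit <- fit_mass_gain(dplyr::select(meta, -".att"), mk_mass_trips(meta))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_model_result(fit, csv, js)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(back$term, tidy(fit)$term)
  man <- jsonlite::read_json(js)
  expect_equal(man$model, "mass_gain")
  expect_true(is.logical(man$converged) || man$converged %in% c(TRUE, FALSE))
})

test_that("terms involving constant covariates are dropped with a message", {
  trips <- mk_trips()
  trips$sex <- "M"
  d <- build_design("encounter_rate", trips = trips)
  expect_message(
    fit <- fit_with_pruning("encounter_rate", d, alpha = 0.05),
    "no variation"
  )
  labs <- attr(stats::terms(fit$formula), "term.labels")
  expect_false(any(grepl("sex", labs)))
})
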