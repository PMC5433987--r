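#' Specifications of the response models
#'
#' The analysis fits five regression models of the behavioural response to
#' vessels, plus a mass-gain model:
#'
#' * `encounter_rate` - number of retained encounter events per trip,
#'   negative binomial with `log(trip duration)` offset, random intercept
#'   per bird; covariate: average number of boats present over the shelf
#'   during the trip.
#' * `attend_prob` - whether an encounter contained attendance, binomial,
#'   random intercepts per bird and trip; activity covariate: time to the
#'   closest fishing operation at the encounter start.
#' * `attend_duration` - number of attendance fixes per attended encounter,
#'   negative binomial.
#' * `attend_prop` - attendance fixes offset by `log(encounter length)`,
#'   negative binomial.
#' * `attend_distance` - mean bird-vessel distance while attending (m),
#'   Gaussian.
#' * `mass_gain` - mass gained at sea (g), ordinary linear model without
#'   random effects.
#'
#' All models include age, sex and their interaction; the encounter-level
#' models add the season group (`2013` vs `2011-12`) with its age and sex
#' interactions and the average number of boats within attraction range
#' during the encounter. Non-significant first-order interactions are pruned
#' sequentially (worst first) at level `alpha`; main effects and random
#' terms are never removed.
#'
#' @param name One of the model names above.
#' @return A list describing response, family, offset, fixed terms and
#'   random grouping.
#' @export
model_spec <- function(name = c("encounter_rate", "attend_prob",
                                "attend_duration", "attend_prop",
                                "attend_distance", "mass_gain")) {
  name <- match.arg(name)
  base_encounter <- c("age", "sex", "year_group", "age:sex",
                      "year_group:age", "year_group:sex",
                      "avg_boats_in_range")
  switch(name,
    encounter_rate = list(
      name = name, response = "n_encounters", family = "nbinom2",
      offset = "log(duration_days)",
      fixed = c("age", "sex", "age:sex", "avg_boats_present"),
      random = "(1 | bird_id)", level = "trip"
    ),
    attend_prob = list(
      name = name, response = "has_attendance", family = "binomial",
      offset = NULL,
      fixed = c(base_encounter, "time_to_fishing"),
      random = "(1 | bird_id) + (1 | trip_id)", level = "encounter"
    ),
    attend_duration = list(
      name = name, response = "n_attendance", family = "nbinom2",
      offset = NULL,
      fixed = c(base_encounter, "prop_fishing"),
      random = "(1 | bird_id) + (1 | trip_id)", level = "attended"
    ),
    attend_prop = list(
      name = name, response = "n_attendance", family = "nbinom2",
      offset = "log(n_locations)",
      fixed = c(base_encounter, "prop_fishing"),
      random = "(1 | bird_id) + (1 | trip_id)", level = "attended"
    ),
    attend_distance = list(
      name = name, response = "mean_distance_m", family = "gaussian",
      offset = NULL,
      fixed = c(base_encounter, "prop_fishing"),
      random = "(1 | bird_id) + (1 | trip_id)", level = "attended"
    ),
    mass_gain = list(
      name = name, response = "mass_gain", family = "gaussian",
      offset = NULL,
      fixed = c("year", "sex", "attendance_prop", "sex:attendance_prop",
                "departure_anomaly"),
      random = NULL, level = "bird"
    )
  )
}

#' Build the model frame for a response model
#'
#' Assembles the rows and columns the chosen model needs from the trip
#' summaries and/or the event covariate table, dropping rows with missing
#' covariates (with a message giving the count). Encounter-level models use
#' retained (daylight-flying) events only; the attendance-behaviour models
#' additionally keep only events that contained attendance.
#'
#' @param name A model name, see [model_spec()].
#' @param trips Output of [trip_summary()].
#' @param events Output of [event_covariates()].
#' @return A tibble ready for [fit_with_pruning()].
#' @export
build_design <- function(name, trips = NULL, events = NULL) {
  spec <- model_spec(name)
  df <- switch(spec$level,
    trip = trips,
    encounter = filter(events, .data$retained_daylight),
    attended = filter(events, .data$retained_daylight,
                      .data$has_attendance),
    bird = abort("Use fit_mass_gain() for the mass model.")
  )
  if (is.null(df)) abort(sprintf("Model '%s' needs its input table.", name))
  vars <- unique(c(
    spec$response,
    all.vars(as.formula(paste("~", paste(spec$fixed, collapse = "+")))),
    if (!is.null(spec$offset)) all.vars(as.formula(paste("~", spec$offset))),
    intersect(c("bird_id", "trip_id"), names(df))
  ))
  df <- select(df, all_of(vars))
  keep <- complete.cases(df)
  if (any(!keep)) {
    message(sprintf("%d row(s) with missing covariates dropped from '%s'.",
                    sum(!keep), name))
  }
  df <- df[keep, ]
  if (spec$response == "has_attendance") {
    df$has_attendance <- as.integer(df$has_attendance)
  }
  for (nm in names(df)) {
    if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  }
  df
}

#' Fit a model, pruning non-significant first-order interactions
#'
#' Fits the full model, then repeatedly removes the least-significant
#' interaction term whose p-value exceeds `alpha` and refits, until every
#' remaining interaction is significant or none remain. Main effects and
#' random terms are never removed. Interaction p-values are Wald chi-square
#' tests for the non-Gaussian mixed models and likelihood-ratio tests for
#' Gaussian responses; the procedure depends only on the fitted terms, so it
#' is invariant to row order.
#'
#' If a mixed fit fails to converge, the model is refitted without random
#' effects and flagged (`converged = FALSE` on the random-effects fit is
#' recorded in the result).
#'
#' @param spec A [model_spec()] list (or model name).
#' @param data Model frame from [build_design()].
#' @param alpha Pruning significance level.
#' @return An object of class `vb_fit`.
#' @export
fit_with_pruning <- function(spec, data, alpha = 0.05) {
  if (is.character(spec)) spec <- model_spec(spec)
  fixed <- drop_degenerate_terms(spec$fixed, data)
  path <- list()
  repeat {
    fit <- fit_engine(spec, fixed, data)
    inter <- grep(":", fixed, value = TRUE)
    if (!length(inter)) break
    pv <- vapply(inter, function(tm) term_p_value(fit, tm, spec, fixed, data),
                 numeric(1))
    pv[!is.finite(pv)] <- 1
    worst <- which.max(pv)
    if (pv[worst] <= alpha) break
    path[[length(path) + 1]] <- tibble(term = inter[worst],
                                       p_at_removal = pv[worst])
    fixed <- setdiff(fixed, inter[worst])
  }
  structure(
    list(
      name = spec$name,
      spec = spec,
      fit = fit$model,
      formula = fit$formula,
      family = spec$family,
      mixed = fit$mixed,
      converged = fit$converged,
      pruned = if (length(path)) bind_rows(path) else
        tibble(term = character(), p_at_removal = numeric()),
      data = data,
      alpha = alpha
    ),
    class = "vb_fit"
  )
}

# drop terms involving constant variables or single-level factors, which
# would make the design matrix rank-deficient by construction
drop_degenerate_terms <- function(fixed, data) {
  degen <- names(data)[vapply(data, function(x) {
    length(unique(x[!is.na(x)])) < 2
  }, logical(1))]
  if (!length(degen)) return(fixed)
  bad <- vapply(fixed, function(tm) {
    any(strsplit(tm, ":")[[1]] %in% degen)
  }, logical(1))
  if (any(bad)) {
    message(sprintf("Dropping term(s) with no variation: %s",
                    paste(fixed[bad], collapse = ", ")))
  }
  fixed[!bad]
}

build_formula <- function(spec, fixed, mixed = TRUE) {
  rhs <- paste(fixed, collapse = " + ")
  if (!is.null(spec$offset)) {
    rhs <- paste(rhs, sprintf("offset(%s)", spec$offset), sep = " + ")
  }
  if (mixed && !is.null(spec$random)) {
    rhs <- paste(rhs, spec$random, sep = " + ")
  }
  as.formula(paste(spec$response, "~", rhs))
}

fit_engine <- function(spec, fixed, data) {
  if (is.null(spec$random)) {
    f <- build_formula(spec, fixed, mixed = FALSE)
    m <- stats::lm(f, data = data)
    return(list(model = m, formula = f, mixed = FALSE, converged = TRUE))
  }
  f <- build_formula(spec, fixed, mixed = TRUE)
  fam <- switch(spec$family,
    nbinom2 = glmmTMB::nbinom2(),
    binomial = stats::binomial(),
    gaussian = stats::gaussian()
  )
  m <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(f, data = data, family = fam)),
    error = function(e) NULL
  )
  ok <- !is.null(m) && isTRUE(m$fit$convergence == 0) &&
    isTRUE(m$sdr$pdHess)
  if (ok) {
    return(list(model = m, formula = f, mixed = TRUE, converged = TRUE))
  }
  # honest degradation: same family without random effects, flagged
  f0 <- build_formula(spec, fixed, mixed = FALSE)
  m0 <- suppressWarnings(glmmTMB::glmmTMB(f0, data = data, family = fam))
  list(model = m0, formula = f0, mixed = FALSE, converged = FALSE)
}

# p-value for a fixed-effect term: joint Wald chi-square on its coefficient
# block, except Gaussian responses where a likelihood-ratio refit is used
term_p_value <- function(fit, term, spec, fixed, data) {
  if (spec$family == "gaussian") {
    reduced <- fit_engine(spec, setdiff(fixed, term), data)
    ll1 <- as.numeric(logLik(fit$model))
    ll0 <- as.numeric(logLik(reduced$model))
    df <- attr(logLik(fit$model), "df") - attr(logLik(reduced$model), "df")
    return(pchisq(2 * (ll1 - ll0), df = max(df, 1), lower.tail = FALSE))
  }
  b <- fixef_vb(fit$model)
  V <- vcov_vb(fit$model)
  idx <- term_coef_index(fit$model, term, fixed, data)
  if (!length(idx)) return(1)
  bi <- b[idx]
  Vi <- V[idx, idx, drop = FALSE]
  stat <- drop(t(bi) %*% solve(Vi) %*% bi)
  pchisq(stat, df = length(idx), lower.tail = FALSE)
}

fixef_vb <- function(m) {
  if (inherits(m, "glmmTMB")) glmmTMB::fixef(m)$cond else stats::coef(m)
}

vcov_vb <- function(m) {
  if (inherits(m, "glmmTMB")) stats::vcov(m)$cond else stats::vcov(m)
}

# indices of the coefficients belonging to one term label
term_coef_index <- function(m, term, fixed, data) {
  ff <- as.formula(paste("~", paste(fixed, collapse = " + ")))
  tt <- stats::terms(ff, data = data)
  labels <- attr(tt, "term.labels")
  k <- match(term, labels)
  if (is.na(k)) {
    # interaction labels may be reordered (a:b vs b:a)
    split_sort <- function(x) paste(sort(strsplit(x, ":")[[1]]),
                                    collapse = ":")
    k <- match(split_sort(term), vapply(labels, split_sort, character(1)))
  }
  if (is.na(k)) return(integer())
  mm <- stats::model.matrix(tt, data = stats::model.frame(tt, data))
  which(attr(mm, "assign") == k &
          colnames(mm) %in% names(fixef_vb(m)))
}

#' Fit the mass-gain model
#'
#' Models the net mass gained at sea (g) as a function of season, sex, the
#' proportion of the trip spent attending vessels, their interaction, and
#' the within-sex anomaly in departure mass. Mass measurements taken on the
#' nest are first corrected for nest mass loss
#' (`params$nest_mass_loss_rate`, g/day) using the optional
#' `days_on_nest_pre` / `days_on_nest_post` columns of `bird_meta` (days
#' between weighing and departure, and between return and re-weighing).
#' One record per bird is required; birds with a missing mass are dropped.
#'
#' @param bird_meta Tibble with `bird_id, sex, age, year, mass_departure,
#'   mass_return` (and optionally the nest-days columns).
#' @param trips Output of [trip_summary()]; each weighed bird must have
#'   exactly one trip there.
#' @param params An [analysis_params()].
#' @param alpha Pruning level for the sex by attendance interaction.
#' @return A `vb_fit` object.
#' @export
fit_mass_gain <- function(bird_meta, trips, params = analysis_params(),
                          alpha = NULL) {
  if (is.null(alpha)) alpha <- params$alpha
  rate <- params$nest_mass_loss_rate
  df <- bird_meta |>
    filter(!is.na(.data$mass_departure), !is.na(.data$mass_return))
  if (anyDuplicated(df$bird_id)) {
    abort("One record per bird is required for the mass-gain model.")
  }
  multi <- trips |> count(.data$bird_id) |> filter(.data$n > 1)
  if (nrow(multi)) {
    warn(sprintf(
      "%d bird(s) have several trips; using each bird's first trip.",
      nrow(multi)
    ))
  }
  trips1 <- trips |>
    group_by(.data$bird_id) |>
    slice(1) |>
    ungroup()
  pre <- if ("days_on_nest_pre" %in% names(df)) df$days_on_nest_pre else 0
  post <- if ("days_on_nest_post" %in% names(df)) df$days_on_nest_post else 0
  df <- df |>
    mutate(
      dep_corr = .data$mass_departure - rate * pre,
      ret_corr = .data$mass_return + rate * post,
      mass_gain = .data$ret_corr - .data$dep_corr
    ) |>
    inner_join(select(trips1, "bird_id", "attendance_prop_of_trip"),
               by = "bird_id") |>
    rename(attendance_prop = "attendance_prop_of_trip") |>
    group_by(.data$sex) |>
    mutate(departure_anomaly = .data$dep_corr - mean(.data$dep_corr)) |>
    ungroup() |>
    mutate(sex = factor(.data$sex), year = factor(.data$year))
  if (any(table(df$sex) < 2) || length(unique(df$sex)) < 2) {
    abort("Need at least two weighed birds of each sex.")
  }
  fit_with_pruning(model_spec("mass_gain"), df, alpha = alpha)
}

#' Fit one of the behavioural response models end to end
#'
#' Convenience wrapper: builds the design with [build_design()] and fits it
#' with [fit_with_pruning()].
#'
#' @param name Model name (see [model_spec()]).
#' @param trips,events Analysis tables.
#' @param params An [analysis_params()] (supplies `alpha`).
#' @return A `vb_fit` object.
#' @export
fit_response_model <- function(name, trips = NULL, events = NULL,
                               params = analysis_params()) {
  df <- build_design(name, trips = trips, events = events)
  fit_with_pruning(model_spec(name), df, alpha = params$alpha)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed-effect estimates of a fitted response model
#'
#' @param x A `vb_fit` object.
#' @param ... Unused.
#' @return A tibble with `term, estimate, std.error, statistic, p.value`.
#' @export
tidy.vb_fit <- function(x, ...) {
  m <- x$fit
  co <- if (inherits(m, "glmmTMB")) {
    summary(m)$coefficients$cond
  } else {
    summary(m)$coefficients
  }
  tibble(
    term = rownames(co),
    estimate = co[, 1],
    std.error = co[, 2],
    statistic = co[, 3],
    p.value = co[, 4]
  )
}

#' One-row model summary
#'
#' @param x A `vb_fit` object.
#' @param ... Unused.
#' @return A tibble with model name, family, n, group counts, whether the
#'   mixed fit converged, the pruned terms, AIC and log-likelihood.
#' @export
glance.vb_fit <- function(x, ...) {
  d <- x$data
  tibble(
    model = x$name,
    family = x$family,
    nobs = nrow(d),
    n_birds = if ("bird_id" %in% names(d)) n_distinct(d$bird_id) else NA_integer_,
    n_trips = if ("trip_id" %in% names(d)) n_distinct(d$trip_id) else NA_integer_,
    mixed = x$mixed,
    converged = x$converged,
    n_pruned = nrow(x$pruned),
    AIC = as.numeric(stats::AIC(x$fit)),
    logLik = as.numeric(logLik(x$fit))
  )
}

#' @export
print.vb_fit <- function(x, ...) {
  cat(sprintf("<vb_fit: %s (%s%s)>\n", x$name, x$family,
              if (x$mixed) ", mixed" else ""))
  cat("  formula: ", deparse(x$formula), "\n")
  if (nrow(x$pruned)) {
    cat("  pruned  : ",
        paste(sprintf("%s (p=%.3f)", x$pruned$term, x$pruned$p_at_removal),
              collapse = ", "), "\n")
  }
  if (!x$converged) {
    cat("  note    : mixed fit did not converge;",
        "refitted without random effects\n")
  }
  print(tidy(x))
  invisible(x)
}

#' Serialise a fitted model to CSV and a JSON manifest
#'
#' Writes the coefficient table (`term, estimate, std.error, statistic,
#' p.value`) as CSV and a JSON manifest recording the final formula, the
#' pruning path, sample sizes and the convergence flag.
#'
#' @param x A `vb_fit`.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, `x`.
#' @export
write_model_result <- function(x, csv_path, json_path) {
  readr::write_csv(tidy(x), csv_path)
  jsonlite::write_json(
    list(
      model = x$name,
      formula = paste(deparse(x$formula), collapse = " "),
      family = x$family,
      mixed = x$mixed,
      converged = x$converged,
      pruned = x$pruned,
      n = as.list(glance(x)[c("nobs", "n_birds", "n_trips")])
    ),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(x)
}
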