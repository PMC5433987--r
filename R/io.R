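#' Read and write the pipeline's CSV dialects
#'
#' Plain-text interchange formats for the four inputs: bird GPS fixes, bird
#' metadata, vessel VMS fixes, and fishing-operation records. Timestamps are
#' ISO-8601 and interpreted as UTC. The synthetic-data generator writes the
#' same dialects, so simulated scenarios exercise the real I/O path.
#'
#' @param path File path.
#' @return A tibble; see Details for the column contract of each reader.
#'
#' @details
#' * `read_bird_tracks()`: `bird_id, trip_id, timestamp, lat, lon`.
#' * `read_bird_meta()`: `bird_id, sex, age, year, mass_departure,
#'   mass_return` (the mass columns may be absent or empty).
#' * `read_vms()`: `vessel_id, timestamp, lat, lon`.
#' * `read_operations()`: `vessel_id, op_type, t_start, t_end, lat_start,
#'   lon_start, lat_end, lon_end` with `op_type` one of `setting`, `hauling`.
#' @name vesselbird-io
NULL

#' @rdname vesselbird-io
#' @export
read_bird_tracks <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("bird_id", "trip_id", "timestamp", "lat", "lon")
  check_cols(x, need, "bird tracks")
  x <- mutate(x,
    bird_id = as.character(.data$bird_id),
    trip_id = as.character(.data$trip_id),
    timestamp = as_utc(.data$timestamp)
  )
  check_lonlat(x$lon, x$lat)
  arrange(x, .data$bird_id, .data$trip_id, .data$timestamp)
}

#' @rdname vesselbird-io
#' @export
read_bird_meta <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(x, c("bird_id", "sex", "age", "year"), "bird metadata")
  # an all-female column reads back as logical (F == FALSE); undo that
  if (is.logical(x$sex)) x$sex <- ifelse(x$sex, "T", "F")
  if (!all(x$sex %in% c("M", "F"))) abort("`sex` must be 'M' or 'F'.")
  mutate(x,
    bird_id = as.character(.data$bird_id),
    year = as.character(.data$year)
  )
}

#' @rdname vesselbird-io
#' @export
read_vms <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(x, c("vessel_id", "timestamp", "lat", "lon"), "VMS")
  x <- mutate(x,
    vessel_id = as.character(.data$vessel_id),
    timestamp = as_utc(.data$timestamp)
  )
  check_lonlat(x$lon, x$lat)
  arrange(x, .data$vessel_id, .data$timestamp)
}

#' @rdname vesselbird-io
#' @export
read_operations <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("vessel_id", "op_type", "t_start", "t_end",
            "lat_start", "lon_start", "lat_end", "lon_end")
  check_cols(x, need, "operations")
  if (!all(x$op_type %in% c("setting", "hauling"))) {
    abort("`op_type` must be 'setting' or 'hauling'.")
  }
  x <- mutate(x,
    vessel_id = as.character(.data$vessel_id),
    t_start = as_utc(.data$t_start),
    t_end = as_utc(.data$t_end)
  )
  if (any(x$t_start >= x$t_end)) abort("Operations need t_start < t_end.")
  arrange(x, .data$vessel_id, .data$t_start)
}

#' Read a study-region polygon from GeoJSON
#'
#' Accepts a GeoJSON `Polygon` geometry, a `Feature` wrapping one, or a
#' `FeatureCollection` whose first feature is a polygon. Only the outer ring
#' is used.
#'
#' @param path Path to a GeoJSON file.
#' @return A tibble with `lon`, `lat` columns.
#' @export
read_region <- function(path) {
  g <- jsonlite::read_json(path)
  if (identical(g$type, "FeatureCollection")) g <- g$features[[1]]
  if (identical(g$type, "Feature")) g <- g$geometry
  if (!identical(g$type, "Polygon")) {
    abort("Region file must contain a GeoJSON Polygon.")
  }
  ring <- g$coordinates[[1]]
  tibble(
    lon = vapply(ring, function(p) as.numeric(p[[1]]), numeric(1)),
    lat = vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
  )
}

#' Write scenario tables as the standard CSV dialects
#'
#' Writes the bird-track, bird-metadata, VMS and operations tables of a
#' simulated scenario (see [simulate_scenario()]) into a directory, using the
#' same formats the readers expect.
#'
#' @param scenario A list as returned by [simulate_scenario()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_scenario_csv <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  files <- c(
    bird_tracks = file.path(dir, "bird_tracks.csv"),
    bird_meta = file.path(dir, "bird_meta.csv"),
    vms = file.path(dir, "vms.csv"),
    operations = file.path(dir, "operations.csv")
  )
  readr::write_csv(
    mutate(scenario$bird_tracks, timestamp = fmt(.data$timestamp)) |>
      select("bird_id", "trip_id", "timestamp", "lat", "lon"),
    files[["bird_tracks"]]
  )
  readr::write_csv(scenario$bird_meta, files[["bird_meta"]])
  readr::write_csv(
    mutate(scenario$vms, timestamp = fmt(.data$timestamp)) |>
      select("vessel_id", "timestamp", "lat", "lon"),
    files[["vms"]]
  )
  readr::write_csv(
    mutate(scenario$operations,
           t_start = fmt(.data$t_start), t_end = fmt(.data$t_end)) |>
      select("vessel_id", "op_type", "t_start", "t_end",
             "lat_start", "lon_start", "lat_end", "lon_end"),
    files[["operations"]]
  )
  invisible(files)
}

check_cols <- function(x, need, what) {
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("%s file is missing column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  }
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                   "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d"))
  if (any(is.na(out) & !is.na(x))) abort("Unparseable timestamp(s).")
  out
}
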