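#' Run the full interaction analysis on one dataset
#'
#' Chains the pipeline stages: vessel merging and interpolation, the
#' bird-vessel spatiotemporal join, encounter segmentation, the
#' daylight-flying filter, event covariates and trip summaries.
#'
#' @param bird_tracks,bird_meta,vms,operations The four input tables (see
#'   [read_bird_tracks()] and friends for the column contracts).
#' @param params An [analysis_params()].
#' @return A list with `vessel_tracks`, `matched`, `events` (with
#'   covariates), and `trips`.
#' @examples
#' ex <- two_encounter_example()
#' res <- analyse_interactions(ex$bird_tracks, ex$bird_meta,
#'                             ex$vms, ex$operations)
#' res$events[, c("event_index", "n_locations", "n_attendance")]
#' @export
analyse_interactions <- function(bird_tracks, bird_meta, vms, operations,
                                 params = analysis_params()) {
  vt <- interpolate_vessel_tracks(vms, operations,
                                  vessel_dt = params$vessel_dt)
  matched <- match_locations(bird_tracks, vt, params)
  events <- segment_encounters(matched, params) |>
    filter_daylight_flying(params) |>
    event_covariates(matched, operations, bird_meta, params)
  trips <- trip_summary(matched, events, vt, bird_meta, params)
  list(vessel_tracks = vt, matched = matched, events = events, trips = trips)
}
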