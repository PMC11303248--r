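# Plain-text interchange: trace/event CSVs, ground-truth JSON sidecars,
# parameter configs (YAML), bout/speed/curve tables.

#' Write / read a uniformly sampled sensor trace as CSV
#'
#' CSV dialect: header `time_s,value`, UTF-8, '.' decimal, uniform sampling.
#'
#' @param trace A `sensor_trace`.
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  tt <- trace$start_time + (seq_along(trace$values) - 1L) / trace$sample_rate
  utils::write.csv(data.frame(time_s = tt, value = trace$values), path,
                   row.names = FALSE)
}

#' @rdname write_trace_csv
#' @param path File path.
#' @return `read_trace_csv()` returns a `sensor_trace` (without rendering
#'   ground truth).
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(d)), nrow(d) >= 2)
  dt <- diff(d$time_s)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("trace is not uniformly sampled")
  structure(list(start_time = d$time_s[1], sample_rate = 1 / stats::median(dt),
                 values = d$value, truth = NULL, overlap_flag = FALSE),
            class = "sensor_trace")
}

#' Write / read an intercept event stream as CSV
#'
#' CSV dialect: header `time_s`, strictly increasing times.
#'
#' @param events An [intercept_series()].
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "intercept_series"))
  utils::write.csv(data.frame(time_s = events$times), path, row.names = FALSE)
}

#' @rdname write_events_csv
#' @param source Source label for the series read back.
#' @export
read_events_csv <- function(path, source = "detected") {
  d <- utils::read.csv(path)
  stopifnot("time_s" %in% names(d))
  intercept_series(d$time_s, source)
}

#' Write / read a ground-truth sidecar as JSON
#'
#' Stores revolution times, distance, the generating parameters and the
#' seed alongside an exported session.
#'
#' @param session A [simulate_session()] result.
#' @param path File path.
#' @export
write_ground_truth_json <- function(session, path) {
  tr <- session$truth
  jsonlite::write_json(list(
    true_revolution_times = tr$true_revolution_times,
    true_distance = tr$true_distance,
    n_revolutions = tr$n_revolutions,
    behavior = unclass(tr$behavior),
    wheel = list(n_rungs = tr$wheel$n_rungs,
                 rung_angles = tr$wheel$rung_angles,
                 circumference = tr$wheel$circumference,
                 pattern = tr$wheel$pattern),
    seed = tr$seed
  ), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read a parameter configuration as YAML
#'
#' One document mirroring the behavior / sensor / wheel parameter field
#' names.
#'
#' @param behavior A [behavior_params()] object (or `NULL`).
#' @param sensor A [sensor_params()] object (or `NULL`).
#' @param wheel A [make_wheel()] geometry (or `NULL`).
#' @param path File path.
#' @export
write_config_yaml <- function(path, behavior = NULL, sensor = NULL,
                              wheel = NULL) {
  cfg <- list()
  if (!is.null(behavior)) cfg$behavior <- unclass(behavior)
  if (!is.null(sensor)) cfg$sensor <- unclass(sensor)
  if (!is.null(wheel)) cfg$wheel <- list(n_rungs = wheel$n_rungs,
                                         rung_angles = wheel$rung_angles,
                                         circumference = wheel$circumference,
                                         pattern = wheel$pattern)
  yaml::write_yaml(cfg, path, precision = 15)
}

#' @rdname write_config_yaml
#' @return `read_config_yaml()` returns a list with any of `behavior`
#'   ([behavior_params()]), `sensor` ([sensor_params()]) and `wheel`
#'   (`wheel_geometry`) reconstructed from the file.
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$behavior)) out$behavior <- do.call(behavior_params, cfg$behavior)
  if (!is.null(cfg$sensor)) out$sensor <- do.call(sensor_params, cfg$sensor)
  if (!is.null(cfg$wheel)) {
    w <- cfg$wheel
    out$wheel <- structure(list(n_rungs = as.integer(w$n_rungs),
                                rung_angles = unlist(w$rung_angles),
                                circumference = w$circumference,
                                pattern = w$pattern),
                           class = "wheel_geometry")
    validate_wheel(out$wheel)
  }
  out
}

#' Write derived telemetry tables as CSV
#'
#' Bout tables are written as `bout_id,t_start_s,t_end_s,n_events`,
#' revolutions as `rev_index,completion_time_s`, speed series as
#' `t_s,rev_index,dist_m,speed_raw,speed_smooth` and curves as
#' `animal_id,group,bin_lo_km,bin_hi_km,velocity`.
#'
#' @param bouts,revs,speeds,curve The corresponding pipeline outputs.
#' @param path File path.
#' @export
write_bouts_csv <- function(bouts, path) {
  utils::write.csv(data.frame(bout_id = bouts$bout_id,
                              t_start_s = bouts$t_start,
                              t_end_s = bouts$t_end,
                              n_events = bouts$n_events),
                   path, row.names = FALSE)
}

#' @rdname write_bouts_csv
#' @export
write_revolutions_csv <- function(revs, path) {
  utils::write.csv(data.frame(rev_index = seq_along(revs$completion_times),
                              completion_time_s = revs$completion_times),
                   path, row.names = FALSE)
}

#' @rdname write_bouts_csv
#' @export
write_speeds_csv <- function(speeds, path) {
  utils::write.csv(data.frame(t_s = speeds$t_s, rev_index = speeds$rev_index,
                              dist_m = speeds$dist_m,
                              speed_raw = speeds$speed,
                              speed_smooth = if ("speed_smooth" %in% names(speeds))
                                speeds$speed_smooth else NA_real_),
                   path, row.names = FALSE)
}

#' @rdname write_bouts_csv
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
}
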