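# Distance, sliding-window speed, smoothing and distance-binned learning
# curves.

#' Cumulative distance from reconstructed revolutions
#'
#' A step function that increases by one circumference at each revolution
#' completion; the final value is exactly `revolutions * circumference`.
#'
#' @param revs A `revolution_series` from [count_revolutions()].
#' @param circumference Wheel circumference, meters.
#' @return Data frame `time_s`, `distance_m` (one row per revolution).
#' @export
cumulative_distance <- function(revs, circumference) {
  stopifnot(inherits(revs, "revolution_series"), circumference > 0)
  n <- length(revs$completion_times)
  data.frame(time_s = revs$completion_times,
             distance_m = seq_len(n) * circumference)
}

#' Sliding-window wheel speed from intercept times
#'
#' Each window spans `n_rungs + 1` consecutive filtered intercepts, i.e.
#' exactly one circumference of rotation regardless of the rung spacing
#' pattern; speed is the circumference divided by the window's elapsed time,
#' reported in m/min. Windows never span a bout boundary, so bouts with fewer
#' than `n_rungs + 1` events contribute no estimate.
#'
#' @param bouts Bout table from [segment_active()].
#' @param events The [intercept_series()] the bouts index into.
#' @param wheel A [make_wheel()] geometry.
#' @param timestamp Report each window at its `"end"` (default) or
#'   `"midpoint"` time.
#' @return Data frame of class `speed_series`: `t_s`, `rev_index` (cumulative
#'   revolutions at window end, fractional), `dist_m` (cumulative distance at
#'   window end), `speed` (m/min). Attributes `n_rungs`, `circumference`.
#' @export
sliding_speed <- function(bouts, events, wheel,
                          timestamp = c("end", "midpoint")) {
  validate_wheel(wheel)
  stopifnot(inherits(events, "intercept_series"))
  timestamp <- match.arg(timestamp)
  n <- wheel$n_rungs
  C <- wheel$circumference
  pieces <- lapply(seq_len(nrow(bouts)), function(b) {
    i0 <- bouts$i_start[b]; i1 <- bouts$i_end[b]
    len <- i1 - i0 + 1L
    if (len < n + 1L) return(NULL)
    tt <- events$times[i0:i1]
    span <- tt[(n + 1L):len] - tt[1:(len - n)]
    if (any(span <= 0)) stop("zero or negative window time span (duplicate timestamps?)")
    gidx_prev <- sum(bouts$n_events[seq_len(b - 1L)])  # filtered events before this bout
    gend <- gidx_prev + (n + 1L):len                   # global filtered index at window end
    data.frame(
      t_s = if (timestamp == "end") tt[(n + 1L):len]
            else (tt[(n + 1L):len] + tt[1:(len - n)]) / 2,
      rev_index = gend / n,
      dist_m = gend / n * C,
      speed = C / span * 60
    )
  })
  pieces <- Filter(Negate(is.null), pieces)
  out <- if (length(pieces))
    do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  else
    data.frame(t_s = numeric(0), rev_index = numeric(0),
               dist_m = numeric(0), speed = numeric(0))
  attr(out, "n_rungs") <- n
  attr(out, "circumference") <- C
  class(out) <- c("speed_series", "data.frame")
  out
}

#' Smooth a speed series by a revolution-window moving average
#'
#' Centered moving average over all entries whose revolution index lies
#' within `window_revolutions / 2` of the current entry's; the window shrinks
#' near the edges of the record (minimum one entry). Times and distances are
#' unchanged.
#'
#' @param speeds A `speed_series` from [sliding_speed()].
#' @param window_revolutions Smoothing window width, revolutions.
#' @return The input with an added `speed_smooth` column.
#' @export
smooth_speed <- function(speeds, window_revolutions = 100) {
  stopifnot(window_revolutions >= 1)
  rev <- speeds$rev_index
  v <- speeds$speed
  if (!length(v)) {
    speeds$speed_smooth <- numeric(0)
    return(speeds)
  }
  h <- window_revolutions / 2
  lo <- findInterval(rev - h, rev, left.open = TRUE) + 1L  # first j: rev[j] >= rev[i]-h
  hi <- findInterval(rev + h, rev)                         # last  j: rev[j] <= rev[i]+h
  cs0 <- c(0, cumsum(v))
  speeds$speed_smooth <- (cs0[hi + 1L] - cs0[lo]) / (hi - lo + 1L)
  speeds
}

#' Bin smoothed velocity into cumulative-distance intervals
#'
#' Average velocities are reported over defined distance intervals so that
#' mouse-to-mouse comparisons are made at equal total distance traveled. Bins
#' are half-open `[lo, hi)` in km of cumulative distance; a bin the animal
#' never reached is `NA`, and a bin that was reached but contains no window
#' estimate is `NA` with a warning.
#'
#' @param speeds A smoothed `speed_series` (from [smooth_speed()]); if no
#'   `speed_smooth` column is present the raw `speed` is binned.
#' @param bin_edges_km Increasing distance bin edges, km.
#' @param animal_id,group Labels carried into the output.
#' @return Data frame `animal_id`, `group`, `bin_lo_km`, `bin_hi_km`,
#'   `milestone_km` (upper edge, the conventional milestone label),
#'   `velocity` (m/min).
#' @export
bin_velocity_by_distance <- function(speeds, bin_edges_km = seq(0, 7, 0.5),
                                     animal_id = NA_character_,
                                     group = NA_character_) {
  if (any(diff(bin_edges_km) <= 0)) stop("bin edges must be increasing")
  v <- if ("speed_smooth" %in% names(speeds)) speeds$speed_smooth
       else speeds$speed
  d_km <- speeds$dist_m / 1000
  nb <- length(bin_edges_km) - 1L
  idx <- findInterval(d_km, bin_edges_km)       # [lo, hi) half-open
  idx[idx < 1L | idx > nb] <- NA_integer_
  means <- tapply(v, factor(idx, levels = seq_len(nb)), mean)
  reached <- if (length(d_km)) bin_edges_km[seq_len(nb)] < max(d_km) else
    rep(FALSE, nb)
  empty_reached <- reached & is.na(means)
  if (any(empty_reached))
    warning(sprintf("%d reached bin(s) contain no speed estimates",
                    sum(empty_reached)), call. = FALSE)
  data.frame(animal_id = animal_id, group = group,
             bin_lo_km = bin_edges_km[seq_len(nb)],
             bin_hi_km = bin_edges_km[-1L],
             milestone_km = bin_edges_km[-1L],
             velocity = as.numeric(means))
}

#' Run the full telemetry-to-learning-curve pipeline on one session
#'
#' Convenience composition: segment active periods, reconstruct revolutions,
#' estimate sliding-window speeds, smooth, and bin by cumulative distance.
#'
#' @param events An [intercept_series()] (truth or detected).
#' @param wheel A [make_wheel()] geometry.
#' @param bin_edges_km Distance bin edges, km.
#' @param gap_threshold_s Active-period gap threshold, seconds.
#' @param window_revolutions Smoothing window, revolutions.
#' @param animal_id,group Labels for the output curve.
#' @return List with `bouts`, `revolutions`, `distance`, `speeds` (smoothed)
#'   and `curve` (the [bin_velocity_by_distance()] output).
#' @export
session_pipeline <- function(events, wheel, bin_edges_km = seq(0, 7, 0.5),
                             gap_threshold_s = 2.0, window_revolutions = 100,
                             animal_id = NA_character_,
                             group = NA_character_) {
  bouts <- segment_active(events, gap_threshold_s)
  revs <- count_revolutions(bouts, events, wheel$n_rungs)
  dist <- cumulative_distance(revs, wheel$circumference)
  speeds <- smooth_speed(sliding_speed(bouts, events, wheel),
                         window_revolutions)
  curve <- bin_velocity_by_distance(speeds, bin_edges_km, animal_id, group)
  list(bouts = bouts, revolutions = revs, distance = dist, speeds = speeds,
       curve = curve)
}
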