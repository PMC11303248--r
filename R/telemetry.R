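# Raw-trace and event-stream processing: peak detection, active-period
# segmentation (2-s rule), revolution reconstruction.

#' Detect rung intercepts on an analog sensor trace
#'
#' Rung intercepts are local maxima of the trace exceeding a robust
#' threshold, `median + min_prominence_mads * MAD` (raw MAD, no normal
#' consistency scaling), separated by at least a refractory period. The event
#' time is the peak-sample time. Peaks are accepted in order of decreasing
#' amplitude, so when two candidates fall within one refractory period the
#' larger wins.
#'
#' @param trace A `sensor_trace` (see [render_trace()] / [read_trace_csv()]).
#' @param min_prominence_mads Threshold height above the baseline median, in
#'   units of the trace median absolute deviation.
#' @param refractory_s Minimum separation between detected events, seconds;
#'   must be representable at the trace's sampling rate.
#' @return An [intercept_series()] with `source = "detected"`. An
#'   all-constant trace yields an empty series.
#' @export
detect_intercepts <- function(trace, min_prominence_mads = 6,
                              refractory_s = 0.02) {
  stopifnot(inherits(trace, "sensor_trace"))
  if (!is.numeric(refractory_s) || refractory_s <= 0)
    stop("refractory_s must be > 0")
  if (refractory_s < 1 / trace$sample_rate)
    stop("configuration error: sample_rate too low to honor refractory_s")
  v <- trace$values
  if (length(v) < 3L || !all(is.finite(v)))
    stop("trace must hold at least 3 finite samples")
  thr <- stats::median(v) + min_prominence_mads * stats::mad(v, constant = 1)
  nv <- length(v)
  cand <- which(v[2:(nv - 1L)] > v[1:(nv - 2L)] &
                v[2:(nv - 1L)] >= v[3:nv] &
                v[2:(nv - 1L)] > thr) + 1L
  if (!length(cand))
    return(intercept_series(numeric(0), "detected"))
  # refractory enforcement, tallest-first
  cand <- cand[order(v[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept_idx <- integer(0)
  min_gap <- refractory_s * trace$sample_rate
  for (i in cand) {
    if (!length(kept_idx) || all(abs(kept_idx - i) >= min_gap))
      kept_idx <- c(kept_idx, i)
  }
  kept_idx <- sort(kept_idx)
  intercept_series(trace$start_time + (kept_idx - 1L) / trace$sample_rate,
                   "detected")
}

#' Segment an intercept series into active-rotation bouts
#'
#' Active wheel rotation is defined as maximal runs of intercepts whose
#' consecutive gaps are strictly less than `gap_threshold_s` (default 2 s).
#' A gap exactly equal to the threshold splits bouts; isolated events form
#' singleton bouts.
#'
#' @param events An [intercept_series()].
#' @param gap_threshold_s Gap threshold in seconds.
#' @return A data frame with one row per bout: `bout_id`, `i_start`, `i_end`
#'   (index range into the event series), `t_start`, `t_end`, `n_events`.
#' @export
segment_active <- function(events, gap_threshold_s = 2.0) {
  stopifnot(inherits(events, "intercept_series"), gap_threshold_s > 0)
  tt <- events$times
  if (!length(tt))
    return(data.frame(bout_id = integer(0), i_start = integer(0),
                      i_end = integer(0), t_start = numeric(0),
                      t_end = numeric(0), n_events = integer(0)))
  new_bout <- c(TRUE, diff(tt) >= gap_threshold_s)
  id <- cumsum(new_bout)
  i_start <- which(new_bout)
  i_end <- c(i_start[-1L] - 1L, length(tt))
  data.frame(bout_id = seq_along(i_start), i_start = i_start, i_end = i_end,
             t_start = tt[i_start], t_end = tt[i_end],
             n_events = i_end - i_start + 1L)
}

# indices of events belonging to the given bouts, in order
bout_event_indices <- function(bouts) {
  if (!nrow(bouts)) return(integer(0))
  unlist(lapply(seq_len(nrow(bouts)),
                function(b) seq.int(bouts$i_start[b], bouts$i_end[b])),
         use.names = FALSE)
}

#' Reconstruct wheel revolutions from active-period intercepts
#'
#' One full revolution is identified by a run of rung intercepts equal to the
#' total number of rungs on the wheel: the k-th revolution completes at the
#' time of filtered intercept number `k * n_rungs`. Because the wheel's phase
#' is physically continuous, the counter persists across bout boundaries by
#' default; `reset_per_bout = TRUE` restarts the count in every bout.
#'
#' @param bouts Bout table from [segment_active()].
#' @param events The [intercept_series()] the bouts index into.
#' @param n_rungs Total number of rungs on the wheel.
#' @param reset_per_bout Restart the intercept counter at each bout boundary.
#' @return A `revolution_series`: list with `completion_times`,
#'   `n_rungs_used` and `n_events` (filtered intercept count).
#' @export
count_revolutions <- function(bouts, events, n_rungs, reset_per_bout = FALSE) {
  stopifnot(inherits(events, "intercept_series"))
  if (!is.numeric(n_rungs) || length(n_rungs) != 1L || n_rungs < 2 ||
      n_rungs != round(n_rungs))
    stop("n_rungs must be an integer >= 2")
  idx <- bout_event_indices(bouts)
  tt <- events$times[idx]
  if (reset_per_bout) {
    comp <- unlist(lapply(seq_len(nrow(bouts)), function(b) {
      bt <- events$times[seq.int(bouts$i_start[b], bouts$i_end[b])]
      k <- seq_len(length(bt) %/% n_rungs) * n_rungs
      bt[k]
    }), use.names = FALSE)
  } else {
    k <- seq_len(length(tt) %/% n_rungs) * n_rungs
    comp <- tt[k]
  }
  structure(list(completion_times = comp, n_rungs_used = as.integer(n_rungs),
                 n_events = length(tt)),
            class = "revolution_series")
}

#' @export
print.revolution_series <- function(x, ...) {
  cat(sprintf("<revolution_series> %d revolutions from %d intercepts (%d rungs)\n",
              length(x$completion_times), x$n_events, x$n_rungs_used))
  invisible(x)
}
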