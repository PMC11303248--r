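# Forward model: bout-structured running on a wheel geometry, rendered either
# as exact rung-intercept event times or as an analog sensor trace.

#' Construct an intercept series
#'
#' @param times Strictly increasing event times in seconds.
#' @param source `"truth"` (simulated ground truth) or `"detected"` (from
#'   peak detection on a trace).
#' @return An `intercept_series` object.
#' @export
intercept_series <- function(times, source = c("truth", "detected")) {
  source <- match.arg(source)
  times <- as.numeric(times)
  if (length(times) && (any(!is.finite(times)) || any(diff(times) <= 0)))
    stop("intercept times must be finite and strictly increasing")
  structure(list(times = times, source = source), class = "intercept_series")
}

#' @export
print.intercept_series <- function(x, ...) {
  cat(sprintf("<intercept_series> %d events (%s)", length(x$times), x$source))
  if (length(x$times))
    cat(sprintf(", %.1f-%.1f s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

# Cumulative crossing angles for a wheel starting at phase 0: the strictly
# increasing sequence {rung angle + 2*pi*m} restricted to (0, Inf). Exact
# (indexed, not accumulated), so there is no drift over long sessions.
crossing_angles <- function(wheel, from_k, n_angles) {
  a <- wheel$rung_angles
  if (a[1] == 0) a <- c(a[-1], 2 * pi)   # crossings are strict: angle > 0
  n <- length(a)
  k <- seq.int(from_k, length.out = n_angles)
  2 * pi * ((k - 1L) %/% n) + a[(k - 1L) %% n + 1L]
}

draw_bouts <- function(behavior) {
  dur <- behavior$session_duration
  if (behavior$bout_rate <= 0)
    return(data.frame(t_start = numeric(0), t_end = numeric(0)))
  rate_s <- behavior$bout_rate / 3600
  t <- 0
  starts <- ends <- numeric(0)
  repeat {
    t_start <- t + stats::rexp(1L, rate_s)
    if (t_start >= dur) break
    b_dur <- stats::rlnorm(1L, behavior$bout_duration_log_mean,
                           behavior$bout_duration_log_sd)
    t_end <- min(t_start + b_dur, dur)
    starts <- c(starts, t_start)
    ends <- c(ends, t_end)
    t <- t_end
  }
  data.frame(t_start = starts, t_end = ends)
}

#' Simulate one wheel-running session
#'
#' Event-driven forward model: within each running bout the wheel advances
#' rung-to-rung at an instantaneous velocity equal to the distance-dependent
#' target [learning_velocity()] times multiplicative AR(1) noise. Rotation is
#' forward-only and the wheel phase is continuous across bouts (the wheel
#' stays put between bouts). Intercept times are exactly the times the
#' cumulative wheel angle crosses each rung angle.
#'
#' @param behavior A [behavior_params()] object.
#' @param wheel A [make_wheel()] geometry.
#' @param seed Master integer seed; fans out to independent substreams for
#'   bout structure and velocity noise.
#' @return A list of class `wheel_session` with elements
#'   \describe{
#'     \item{intercepts}{[intercept_series()] of ground-truth event times.}
#'     \item{truth}{Ground truth: `true_revolution_times` (completion time of
#'       each full revolution), `true_distance` (complete revolutions times
#'       circumference, meters), `n_revolutions`, `final_angle` (radians),
#'       `bouts` (true bout table), and the generating parameters.}
#'   }
#' @export
simulate_session <- function(behavior, wheel, seed = 1L) {
  stopifnot(inherits(behavior, "behavior_params"))
  validate_wheel(wheel)
  C <- wheel$circumference
  n <- wheel$n_rungs
  sigma <- sqrt(log(1 + behavior$within_bout_cv^2))
  phi <- behavior$ar1_phi

  bouts <- with_seed(substream_seed(seed, "bouts"), draw_bouts(behavior))

  times <- numeric(0)
  omegas <- numeric(0)
  k0 <- 1L            # next global crossing index
  with_seed(substream_seed(seed, "noise"), {
    for (b in seq_len(nrow(bouts))) {
      t_now <- bouts$t_start[b]
      t_end <- bouts$t_end[b]
      x_prev <- if (sigma > 0) stats::rnorm(1L, 0, sigma) else 0
      theta_prev <- if (k0 == 1L) 0 else crossing_angles(wheel, k0 - 1L, 1L)
      repeat {
        dur_left <- t_end - t_now
        if (dur_left <= 0) break
        # generous chunk: expected crossings at v_max plus headroom
        M <- max(64L, ceiling(2 * dur_left * behavior$v_max / 60 / C * n) + n)
        A <- crossing_angles(wheel, k0, M)
        dtheta <- diff(c(theta_prev, A))
        d_m <- A * C / (2 * pi)   # cumulative distance at each crossing
        v_t <- learning_velocity(d_m / 1000, behavior$v0, behavior$v_max,
                                 behavior$lambda_learn)
        if (sigma > 0) {
          z <- stats::rnorm(M, 0, sigma * sqrt(1 - phi^2))
          x <- as.numeric(stats::filter(z, phi, method = "recursive",
                                        init = x_prev))
          eps <- exp(x - sigma^2 / 2)
        } else {
          x <- rep(0, M)
          eps <- rep(1, M)
        }
        omega <- (v_t * eps) / 60 / C * (2 * pi)   # rad/s
        tt <- t_now + cumsum(dtheta / omega)
        keep <- tt <= t_end
        n_keep <- sum(keep)
        if (n_keep > 0) {
          times <- c(times, tt[seq_len(n_keep)])
          omegas <- c(omegas, omega[seq_len(n_keep)])
          k0 <- k0 + n_keep
          theta_prev <- A[n_keep]
          t_now <- tt[n_keep]
          x_prev <- x[n_keep]
        }
        if (n_keep < M) break   # bout time budget exhausted
      }
    }
  })

  n_events <- k0 - 1L
  final_angle <- if (n_events == 0L) 0 else crossing_angles(wheel, n_events, 1L)
  n_rev <- as.integer(floor(final_angle / (2 * pi)))
  rev_times <- numeric(0)
  if (n_rev >= 1) {
    A_all <- crossing_angles(wheel, 1L, n_events)
    targets <- 2 * pi * seq_len(n_rev)
    # first crossing with A >= target; interpolate within that inter-rung
    # segment at its (constant) angular velocity
    idx <- findInterval(targets, A_all, left.open = TRUE) + 1L
    rev_times <- times[idx] - (A_all[idx] - targets) / omegas[idx]
  }

  structure(list(
    intercepts = intercept_series(times, "truth"),
    truth = list(
      true_intercepts = times,
      true_revolution_times = rev_times,
      true_distance = n_rev * C,
      n_revolutions = n_rev,
      final_angle = final_angle,
      bouts = bouts,
      behavior = behavior, wheel = wheel, seed = seed
    )
  ), class = "wheel_session")
}

#' Exact intercept times for constant-rate rotation
#'
#' Analytic fixture: a wheel rotating at a constant angular velocity produces
#' intercepts exactly where the cumulative angle crosses each rung angle.
#'
#' @param rev_per_s Rotation rate, revolutions per second.
#' @param duration Duration in seconds.
#' @param wheel A [make_wheel()] geometry.
#' @param t0 Start time offset, seconds.
#' @return An [intercept_series()] with `source = "truth"`.
#' @export
constant_rotation_events <- function(rev_per_s, duration, wheel, t0 = 0) {
  validate_wheel(wheel)
  stopifnot(rev_per_s > 0, duration > 0)
  omega <- 2 * pi * rev_per_s
  n_max <- ceiling(duration * rev_per_s + 1) * wheel$n_rungs
  A <- crossing_angles(wheel, 1L, n_max)
  tt <- t0 + A / omega
  intercept_series(tt[tt <= t0 + duration], "truth")
}

#' Render an analog sensor trace from intercept times
#'
#' Emulates the logged infrared rung-sensor output: a uniformly sampled trace
#' equal to Gaussian baseline noise plus one Gaussian-shaped pulse per
#' non-missed intercept plus seeded spurious pulses. The ground-truth pulse
#' bookkeeping (rendered, missed and spurious times) is retained alongside.
#'
#' @param intercepts An [intercept_series()].
#' @param sensor A [sensor_params()] object.
#' @param duration Trace duration, seconds; defaults to the last event plus
#'   one second (or 1 s for an empty series).
#' @param seed Master integer seed (uses the `"sensor"` substream).
#' @return A `sensor_trace`: list with `start_time`, `sample_rate`, `values`,
#'   `truth` (`rendered_times`, `missed_times`, `spurious_times`) and
#'   `overlap_flag` (`TRUE` when two rendered pulses fall closer than half a
#'   pulse width, in which case detection may merge them).
#' @export
render_trace <- function(intercepts, sensor, duration = NULL, seed = 1L) {
  stopifnot(inherits(intercepts, "intercept_series"),
            inherits(sensor, "sensor_params"))
  tt <- intercepts$times
  if (is.null(duration))
    duration <- if (length(tt)) max(tt) + 1 else 1
  rate <- sensor$sample_rate
  n_samp <- floor(duration * rate) + 1L
  grid <- (seq_len(n_samp) - 1L) / rate

  out <- with_seed(substream_seed(seed, "sensor"), {
    missed <- if (length(tt)) stats::runif(length(tt)) < sensor$miss_rate
              else logical(0)
    n_spur <- stats::rpois(1L, sensor$spurious_rate * duration)
    spur <- sort(stats::runif(n_spur, 0, duration))
    pulses <- sort(c(tt[!missed], spur))
    amps <- pmax(sensor$pulse_amplitude *
                   (1 + sensor$amplitude_cv * stats::rnorm(length(pulses))),
                 0.1 * sensor$pulse_amplitude)
    values <- if (sensor$baseline_sd > 0)
      stats::rnorm(n_samp, 0, sensor$baseline_sd) else numeric(n_samp)
    w <- sensor$pulse_width
    half <- ceiling(5 * w * rate)
    for (j in seq_along(pulses)) {
      ic <- round(pulses[j] * rate) + 1L
      lo <- max(1L, ic - half); hi <- min(n_samp, ic + half)
      idx <- lo:hi
      values[idx] <- values[idx] +
        amps[j] * exp(-((grid[idx] - pulses[j])^2) / (2 * w^2))
    }
    list(values = values,
         rendered = tt[!missed], missed = tt[missed], spur = spur,
         overlap = length(pulses) > 1 && any(diff(pulses) < w / 2))
  })

  structure(list(start_time = 0, sample_rate = rate, values = out$values,
                 truth = list(rendered_times = out$rendered,
                              missed_times = out$missed,
                              spurious_times = out$spur),
                 overlap_flag = out$overlap),
            class = "sensor_trace")
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> %d samples @ %g Hz (%.1f s), %d rendered pulses\n",
              length(x$values), x$sample_rate,
              length(x$values) / x$sample_rate,
              length(x$truth$rendered_times)))
  invisible(x)
}
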