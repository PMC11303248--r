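#' Behavioral parameters for a simulated wheel-running session
#'
#' The behavioral model is a renewal process of running bouts (exponential
#' inter-bout gaps, lognormal bout durations) during which the mouse tracks a
#' saturating-exponential target velocity in cumulative distance,
#' \deqn{v(d) = v_0 + (v_{max} - v_0)(1 - e^{-d/\lambda}),}
#' with multiplicative AR(1) noise on the instantaneous velocity within a
#' bout. Learning is indexed by cumulative distance (not wall-clock time), so
#' animals are comparable at equal distance traveled.
#'
#' Defaults describe a mouse housed with the wheel for a week that
#' accumulates roughly 7-8 km: about 1.5 bouts per hour of ~1.5 min, starting
#' near 5 m/min and plateauing near 25 m/min with a learning length constant
#' of 1.4 km.
#'
#' @param session_duration Session length in seconds.
#' @param bout_rate Mean bouts per hour; exponential inter-bout gaps.
#' @param bout_duration_log_mean,bout_duration_log_sd Lognormal parameters of
#'   bout duration in seconds.
#' @param v0 Starting target velocity, m/min.
#' @param v_max Asymptotic target velocity, m/min (>= `v0`).
#' @param lambda_learn Learning length constant, km.
#' @param within_bout_cv Coefficient of variation of instantaneous velocity
#'   within a bout (AR(1) multiplicative noise); 0 disables noise.
#' @param ar1_phi Lag-one autocorrelation of the within-bout noise.
#' @return A `behavior_params` list.
#' @export
behavior_params <- function(session_duration = 7 * 24 * 3600,
                            bout_rate = 1.5,
                            bout_duration_log_mean = log(70),
                            bout_duration_log_sd = 0.7,
                            v0 = 5, v_max = 25,
                            lambda_learn = 1.4,
                            within_bout_cv = 0.1,
                            ar1_phi = 0.9) {
  p <- list(session_duration = session_duration, bout_rate = bout_rate,
            bout_duration_log_mean = bout_duration_log_mean,
            bout_duration_log_sd = bout_duration_log_sd,
            v0 = v0, v_max = v_max, lambda_learn = lambda_learn,
            within_bout_cv = within_bout_cv, ar1_phi = ar1_phi)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                  logical(1))))
    stop("behavior parameters must be finite scalars")
  if (p$session_duration <= 0 || p$bout_rate < 0 ||
      p$bout_duration_log_sd < 0 || p$v0 <= 0 || p$lambda_learn <= 0 ||
      p$within_bout_cv < 0 || p$ar1_phi < 0 || p$ar1_phi >= 1)
    stop("behavior parameters out of range")
  if (p$v0 > p$v_max) stop("v0 must not exceed v_max")
  structure(p, class = "behavior_params")
}

#' Infrared rung-sensor parameters for trace rendering
#'
#' The analog sensor is modeled as emitting one Gaussian-shaped voltage pulse
#' per rung passage on top of additive Gaussian baseline noise, with a small
#' probability of dropped pulses and a low rate of spurious pulses.
#'
#' @param sample_rate Sampling rate in Hz; must exceed `2 / pulse_width` so
#'   pulses are resolvable.
#' @param pulse_width Gaussian pulse standard deviation, seconds.
#' @param pulse_amplitude Mean pulse amplitude, arbitrary units.
#' @param amplitude_cv Relative jitter of pulse amplitudes.
#' @param baseline_sd Additive Gaussian baseline noise sd; the default
#'   emulates a strong-reflectance infrared sensor (SNR ~50 against the
#'   pulse amplitude).
#' @param miss_rate Probability in `[0, 1)` that a rung passage produces no
#'   pulse.
#' @param spurious_rate Expected spurious pulses per second of trace, in
#'   `[0, 1)`.
#' @return A `sensor_params` list.
#' @export
sensor_params <- function(sample_rate = 1000,
                          pulse_width = 0.005,
                          pulse_amplitude = 1,
                          amplitude_cv = 0.1,
                          baseline_sd = 0.02,
                          miss_rate = 0.01,
                          spurious_rate = 0.01) {
  p <- list(sample_rate = sample_rate, pulse_width = pulse_width,
            pulse_amplitude = pulse_amplitude, amplitude_cv = amplitude_cv,
            baseline_sd = baseline_sd, miss_rate = miss_rate,
            spurious_rate = spurious_rate)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                  logical(1))))
    stop("sensor parameters must be finite scalars")
  if (p$sample_rate <= 2 / p$pulse_width)
    stop("sample_rate must exceed 2 / pulse_width (pulses unresolvable)")
  if (p$pulse_width <= 0 || p$pulse_amplitude <= 0 || p$amplitude_cv < 0 ||
      p$baseline_sd < 0)
    stop("sensor parameters out of range")
  if (p$miss_rate < 0 || p$miss_rate >= 1 || p$spurious_rate < 0 ||
      p$spurious_rate >= 1)
    stop("miss_rate and spurious_rate must lie in [0, 1)")
  structure(p, class = "sensor_params")
}

#' Target learning-curve velocity at a cumulative distance
#'
#' Closed form of the saturating-exponential curve family used by the
#' synthetic behavior model.
#'
#' @param d_km Cumulative distance, km (vectorized).
#' @param v0,v_max Starting and asymptotic velocity, m/min.
#' @param lambda_learn Learning length constant, km.
#' @return Target velocity in m/min.
#' @export
learning_velocity <- function(d_km, v0 = 5, v_max = 25, lambda_learn = 1.4) {
  v0 + (v_max - v0) * (1 - exp(-d_km / lambda_learn))
}
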