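# Shared fixtures and independent brute-force oracles. The oracles implement
# each definition directly (loops, explicit formulas) and never call the
# package functions they check.

wheel_regular <- function(n = 38, circ = 0.38) make_wheel(n, circ, "regular")
wheel_complex <- function(seed = 1, n = 22, circ = 0.38)
  make_wheel(n, circ, "complex", seed = seed)

short_behavior <- function(...) {
  defaults <- list(session_duration = 2 * 3600, bout_rate = 8,
                   bout_duration_log_mean = log(60),
                   bout_duration_log_sd = 0.5)
  args <- utils::modifyList(defaults, list(...))
  do.call(behavior_params, args)
}

# direct scan over gaps: start a new bout wherever gap >= threshold
oracle_segment <- function(times, thr = 2) {
  if (!length(times)) return(integer(0))
  id <- integer(length(times))
  id[1] <- 1L
  for (i in seq_along(times)[-1])
    id[i] <- if (times[i] - times[i - 1] < thr) id[i - 1] else id[i - 1] + 1L
  id
}

# O(n * w) window speed: per bout, every run of n_rungs + 1 events
oracle_sliding <- function(bout_ids, times, n_rungs, circ) {
  out <- NULL
  for (b in unique(bout_ids)) {
    tt <- times[bout_ids == b]
    if (length(tt) < n_rungs + 1) next
    for (i in (n_rungs + 1):length(tt))
      out <- rbind(out, c(tt[i], circ / (tt[i] - tt[i - n_rungs]) * 60))
  }
  out
}

# O(n * w) centered revolution-window mean
oracle_smooth <- function(rev, v, w) {
  vapply(seq_along(v), function(i) {
    sel <- rev >= rev[i] - w / 2 & rev <= rev[i] + w / 2
    mean(v[sel])
  }, numeric(1))
}

# explicit Welch t statistic and Welch-Satterthwaite df
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df))
}

# explicit normal equations for simple OLS
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# random event series with gaps straddling the 2-s boundary, including exact
# 2.0-s gaps
random_event_series <- function(seed, n = 60) {
  set.seed(seed)
  gaps <- sample(c(runif(n, 0.05, 1.9), runif(n %/% 3, 2.0, 6),
                   rep(2.0, n %/% 6)))
  intercept_series(cumsum(gaps), "truth")
}
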