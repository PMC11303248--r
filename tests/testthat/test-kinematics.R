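# Cumulative distance, sliding-window speed, smoothing, distance binning.

test_that("cumulative distance is an exact step function of revolutions", {
  r0 <- count_revolutions(segment_active(intercept_series(numeric(0))),
                          intercept_series(numeric(0)), 38)
  expect_equal(nrow(cumulative_distance(r0, 0.38)), 0)

  tt <- cumsum(rep(0.1, 5 * 38))
  ev <- intercept_series(tt)
  revs <- count_revolutions(segment_active(ev), ev, 38)
  d <- cumulative_distance(revs, 0.38)
  expect_identical(tail(d$distance_m, 1), 5 * 0.38)

  # noise-free session: pipeline distance equals ground truth exactly
  w <- wheel_complex(seed = 6)
  s <- simulate_session(short_behavior(within_bout_cv = 0), w, seed = 17)
  b <- segment_active(s$intercepts)
  revs <- count_revolutions(b, s$intercepts, w$n_rungs)
  d <- cumulative_distance(revs, w$circumference)
  expect_identical(tail(d$distance_m, 1), s$truth$true_distance)
})

test_that("constant rotation gives the analytic speed on any rung pattern", {
  circ <- 0.4
  wr <- make_wheel(38, circ, "regular")
  wc <- make_wheel(22, circ, "complex", seed = 2)
  for (w in list(wr, wc)) {
    ev <- constant_rotation_events(0.5, 60, w)
    sp <- sliding_speed(segment_active(ev), ev, w)
    expect_gt(nrow(sp), 0)
    expect_equal(sp$speed, rep(circ * 0.5 * 60, nrow(sp)), tolerance = 1e-12)
  }
})

test_that("windows never span bouts; short bouts yield no estimate", {
  w <- wheel_regular(10, 0.4)
  # bout A: exactly n_rungs events (no window); bout B: n_rungs + 2 events
  tt <- c(cumsum(rep(0.1, 10)), 100 + cumsum(rep(0.1, 12)))
  ev <- intercept_series(tt)
  b <- segment_active(ev)
  sp <- sliding_speed(b, ev, w)
  expect_equal(nrow(sp), 2)            # only bout B, two windows
  expect_true(all(sp$t_s > 100))

  # duplicate timestamps make a window of zero elapsed time: an error
  w2 <- wheel_regular(2, 0.4)
  dup <- intercept_series(c(1, 2, 3))
  dup$times <- c(1, 1, 1)              # bypass constructor validation
  b2 <- data.frame(bout_id = 1, i_start = 1, i_end = 3,
                   t_start = 1, t_end = 1, n_events = 3)
  expect_error(sliding_speed(b2, dup, w2), "span")
})

test_that("sliding speeds match brute-force recomputation to 1e-12", {
  w <- wheel_complex(seed = 7)
  s <- simulate_session(short_behavior(), w, seed = 23)
  b <- segment_active(s$intercepts)
  sp <- sliding_speed(b, s$intercepts, w)
  ids <- rep(b$bout_id, b$n_events)
  oracle <- oracle_sliding(ids, s$intercepts$times, w$n_rungs, w$circumference)
  expect_equal(nrow(sp), nrow(oracle))
  expect_equal(sp$t_s, oracle[, 1], tolerance = 1e-12)
  expect_equal(sp$speed, oracle[, 2], tolerance = 1e-12)
})

test_that("smoothing: identity cases and brute-force equality", {
  # constant series unchanged
  sp <- data.frame(t_s = 1:50, rev_index = (1:50) / 10,
                   dist_m = (1:50) * 0.038, speed = rep(12, 50))
  expect_equal(smooth_speed(sp, 100)$speed_smooth, rep(12, 50))

  # entries one revolution apart: window of 1 revolution touches only itself
  set.seed(1)
  sp1 <- data.frame(t_s = 1:30, rev_index = 1:30, dist_m = (1:30) * 0.38,
                    speed = runif(30, 5, 25))
  expect_equal(smooth_speed(sp1, 1)$speed_smooth, sp1$speed)

  # random fractional revolution grid vs O(n*w) oracle
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(50:400, 1)
    rev <- cumsum(runif(n, 0.01, 0.2))
    spd <- runif(n, 2, 30)
    spr <- data.frame(t_s = seq_len(n), rev_index = rev, dist_m = rev * 0.38,
                      speed = spd)
    wrev <- sample(c(1, 5, 20, 100), 1)
    got <- smooth_speed(spr, wrev)$speed_smooth
    expect_equal(got, oracle_smooth(rev, spd, wrev), tolerance = 1e-12)
  }
})

test_that("smoothing approximately conserves the series mean", {
  set.seed(5)
  n <- 500
  spr <- data.frame(t_s = seq_len(n), rev_index = cumsum(runif(n, 0.02, 0.1)),
                    dist_m = seq_len(n), speed = runif(n, 5, 25))
  sm <- smooth_speed(spr, 10)$speed_smooth
  expect_lt(abs(mean(sm) - mean(spr$speed)), 0.5)
})

test_that("distance binning: constant speed, truncation, empty-bin warning", {
  sp <- data.frame(t_s = 1:100, rev_index = 1:100, dist_m = seq(0, 990, 10),
                   speed = rep(15, 100))
  cur <- bin_velocity_by_distance(sp, seq(0, 1.5, 0.25))
  expect_equal(cur$velocity[1:4], rep(15, 4))
  expect_true(all(is.na(cur$velocity[5:6])))   # never reached beyond 1.0 km

  # animal stops at 3 km: bins above 3 km are missing
  sp2 <- data.frame(t_s = 1:300, rev_index = 1:300,
                    dist_m = seq(0, 2990, 10), speed = rep(10, 300))
  cur2 <- bin_velocity_by_distance(sp2, seq(0, 7, 0.5))
  expect_true(all(!is.na(cur2$velocity[cur2$bin_hi_km <= 3])))
  expect_true(all(is.na(cur2$velocity[cur2$bin_lo_km >= 3])))

  # a reached bin with no windows warns
  sp3 <- data.frame(t_s = 1:2, rev_index = 1:2, dist_m = c(100, 1400),
                    speed = c(10, 10))
  expect_warning(bin_velocity_by_distance(sp3, seq(0, 1.5, 0.5)),
                 "no speed estimates")

  expect_error(bin_velocity_by_distance(sp, c(0, 0.5, 0.5)), "increasing")
})

test_that("quiescent gaps >= 2 s change no speed estimate or bin assignment", {
  w <- wheel_regular(10, 0.4)
  t1 <- cumsum(rep(0.1, 25))
  t2 <- max(t1) + 5 + cumsum(rep(0.12, 25))
  ev <- intercept_series(c(t1, t2))
  b <- segment_active(ev)
  sp <- smooth_speed(sliding_speed(b, ev, w), 2)
  # insert an extra 100 s of quiet between the bouts: speeds and distances
  # are unchanged (times shift in the second bout only)
  ev2 <- intercept_series(c(t1, t2 + 100))
  sp2 <- smooth_speed(sliding_speed(segment_active(ev2), ev2, w), 2)
  expect_equal(sp2$speed, sp$speed)
  expect_equal(sp2$dist_m, sp$dist_m)
  expect_equal(sp2$speed_smooth, sp$speed_smooth)
  cur <- bin_velocity_by_distance(sp, seq(0, 0.02, 0.005))
  cur2 <- bin_velocity_by_distance(sp2, seq(0, 0.02, 0.005))
  expect_equal(cur2$velocity, cur$velocity)
})

test_that("binned pipeline curve recovers the analytic learning curve", {
  # moderate-length session for speed; full-scale recovery is exercised in
  # the acceptance suite
  w <- wheel_complex(seed = 1)
  beh <- behavior_params(session_duration = 2 * 24 * 3600, bout_rate = 4,
                         within_bout_cv = 0.05)
  s <- simulate_session(beh, w, seed = 31)
  res <- session_pipeline(s$intercepts, w, bin_edges_km = seq(0, 2.5, 0.5))
  ok <- !is.na(res$curve$velocity)
  expect_gte(sum(ok), 4)
  mid <- res$curve$milestone_km[ok] - 0.25
  target <- learning_velocity(mid, beh$v0, beh$v_max, beh$lambda_learn)
  rmse <- sqrt(mean((res$curve$velocity[ok] - target)^2))
  expect_lt(rmse, 0.05 * beh$v_max)
})
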