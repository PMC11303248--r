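# Synthetic-data generator: wheel geometries, sessions, traces, cohorts and
# OPC point patterns.

test_that("wheel construction honors pattern, spacing and determinism", {
  w <- wheel_regular(38)
  expect_equal(w$rung_angles, 2 * pi * (0:37) / 38)
  expect_equal(diff(w$rung_angles), rep(2 * pi / 38, 37))

  wc <- wheel_complex(seed = 1)
  expect_length(wc$rung_angles, 22)
  expect_true(all(diff(wc$rung_angles) > 0))
  expect_true(all(wc$rung_angles >= 0 & wc$rung_angles < 2 * pi))
  expect_gt(max(diff(wc$rung_angles)), min(diff(wc$rung_angles)))  # irregular

  expect_identical(wheel_complex(seed = 7), wheel_complex(seed = 7))
  expect_false(identical(wheel_complex(seed = 7)$rung_angles,
                         wheel_complex(seed = 8)$rung_angles))

  expect_error(make_wheel(1, 0.38), "invalid wheel geometry")
  expect_error(make_wheel(10, 0), "invalid wheel geometry")
  expect_error(make_wheel(10, -1), "invalid wheel geometry")
})

test_that("session simulation: no running, analytic constant rotation, determinism", {
  w <- wheel_regular(38)
  s0 <- simulate_session(short_behavior(bout_rate = 0), w, seed = 3)
  expect_length(s0$intercepts$times, 0)
  expect_equal(s0$truth$true_distance, 0)

  # 1 rev/s for 10 s on a 38-rung wheel: 380 intercepts, 10 revolutions
  ev <- constant_rotation_events(1, 10, w)
  expect_length(ev$times, 380)
  expect_equal(max(ev$times), 10)

  s1 <- simulate_session(short_behavior(), w, seed = 11)
  s2 <- simulate_session(short_behavior(), w, seed = 11)
  expect_identical(s1$intercepts$times, s2$intercepts$times)
  expect_identical(s1$truth$true_revolution_times, s2$truth$true_revolution_times)
})

test_that("ground truth is self-consistent and distance matches geometry replay", {
  w <- wheel_complex(seed = 2)
  s <- simulate_session(short_behavior(), w, seed = 42)
  tr <- s$truth
  # conservation: distance = revolutions x circumference, exactly
  expect_identical(tr$true_distance, tr$n_revolutions * w$circumference)
  expect_gte(length(tr$true_intercepts), w$n_rungs * tr$n_revolutions)
  expect_true(all(diff(tr$true_revolution_times) > 0))

  # oracle: replay the event count against the rung lattice to recover the
  # total swept angle, independent of the simulator's internal state
  n_ev <- length(tr$true_intercepts)
  a <- w$rung_angles
  if (a[1] == 0) a <- c(a[-1], 2 * pi)
  angle_oracle <- 2 * pi * ((n_ev - 1) %/% w$n_rungs) + a[(n_ev - 1) %% w$n_rungs + 1]
  expect_equal(tr$final_angle, angle_oracle, tolerance = 1e-12)
  expect_identical(tr$n_revolutions, as.integer(floor(angle_oracle / (2 * pi))))
})

test_that("per-bout mean velocity is nondecreasing when noise is off", {
  w <- wheel_complex(seed = 5)
  s <- simulate_session(short_behavior(within_bout_cv = 0, bout_rate = 10), w,
                        seed = 9)
  bouts <- segment_active(s$intercepts)
  expect_gt(nrow(bouts), 3)
  v_bout <- vapply(seq_len(nrow(bouts)), function(b) {
    tt <- s$intercepts$times[bouts$i_start[b]:bouts$i_end[b]]
    if (length(tt) < 2) return(NA_real_)
    (length(tt) - 1) / (max(tt) - min(tt))   # events/s ~ angular rate proxy
  }, numeric(1))
  v_bout <- v_bout[!is.na(v_bout)]
  # complex rung spacing makes events/s only a proxy; compare bout means with
  # slack of one part in fifty
  expect_true(all(diff(v_bout) > -0.02 * v_bout[-length(v_bout)]))
})

test_that("trace rendering: empty, single pulse, bookkeeping, fidelity", {
  sp0 <- sensor_params(baseline_sd = 0, miss_rate = 0, spurious_rate = 0,
                       amplitude_cv = 0)
  tr0 <- render_trace(intercept_series(numeric(0)), sp0)
  expect_true(all(tr0$values == 0))

  tr1 <- render_trace(intercept_series(1.0), sp0, duration = 2, seed = 1)
  peak_t <- (which.max(tr1$values) - 1) / tr1$sample_rate
  expect_lt(abs(peak_t - 1.0), 0.5 / tr1$sample_rate + 1e-12)

  # seeded bookkeeping: rendered + missed partition the input; spurious lie
  # inside the trace; identical seeds give bit-identical traces
  ev <- intercept_series(seq(0.5, 50, by = 0.1))
  sp <- sensor_params()
  tr <- render_trace(ev, sp, seed = 4)
  expect_setequal(c(tr$truth$rendered_times, tr$truth$missed_times), ev$times)
  expect_true(all(tr$truth$spurious_times >= 0 &
                  tr$truth$spurious_times <= length(tr$values) / tr$sample_rate))
  expect_identical(tr$values, render_trace(ev, sp, seed = 4)$values)
  expect_false(identical(tr$values, render_trace(ev, sp, seed = 5)$values))

  # rendering fidelity: no noise, no misses -> one pulse per intercept
  trc <- render_trace(ev, sp0, seed = 1)
  expect_length(trc$truth$rendered_times, length(ev$times))
  expect_length(trc$truth$missed_times, 0)
  expect_length(trc$truth$spurious_times, 0)
})

test_that("overlap flag raises when pulses are closer than half a pulse width", {
  sp <- sensor_params(pulse_width = 0.05, sample_rate = 500, baseline_sd = 0,
                      miss_rate = 0, spurious_rate = 0)
  expect_true(render_trace(intercept_series(c(1, 1.02)), sp, seed = 1)$overlap_flag)
  expect_false(render_trace(intercept_series(c(1, 1.5)), sp, seed = 1)$overlap_flag)
})

test_that("cohorts: exchangeability, closed-form deficit, monotone coverage link", {
  eq_eff <- list(a = list(v_max_mult = 1, lambda_mult = 1),
                 b = list(v_max_mult = 1, lambda_mult = 1))
  co <- simulate_cohort(300, eq_eff, seed = 2, level = "curve",
                        milestones_km = 7)
  ma <- mean(co$curves$velocity[co$curves$group == "a"])
  mb <- mean(co$curves$velocity[co$curves$group == "b"])
  expect_lt(abs(ma - mb), 0.5)   # equal in expectation, n = 300/group

  # no between-animal spread, lambda shared: difference at distance d is
  # exactly 0.15 * v_max * (1 - exp(-d / lambda))
  eff <- list(ctrl = list(v_max_mult = 1, lambda_mult = 1),
              imp = list(v_max_mult = 0.85, lambda_mult = 1))
  beh <- behavior_params()
  co2 <- simulate_cohort(3, eff, base_behavior = beh, seed = 1,
                         level = "curve", milestones_km = 7,
                         cv_between = 0, milestone_noise_sd = 0)
  d_mid <- 7 - 0.25
  delta <- mean(co2$curves$velocity[co2$curves$group == "ctrl"]) -
    mean(co2$curves$velocity[co2$curves$group == "imp"])
  expect_equal(delta, 0.15 * beh$v_max * (1 - exp(-d_mid / beh$lambda_learn)),
               tolerance = 1e-10)

  # deterministic monotone link, zero noise: coverage vs end velocity has
  # rank correlation exactly -1 (lambda shared so velocity is monotone in
  # the per-animal plateau across both groups)
  co3 <- simulate_cohort(8, eff,
                         coverage_model = coverage_model_default(logit_noise_sd = 0),
                         seed = 6, level = "curve", milestones_km = 7,
                         milestone_noise_sd = 0)
  v7 <- co3$curves$velocity[match(co3$meta$animal_id, co3$curves$animal_id)]
  expect_equal(cor(co3$meta$coverage_percent, v7, method = "spearman"), -1)

  expect_error(simulate_cohort(1, group_effects_default(), seed = 1,
                               level = "curve"), "n_per_group")
})

test_that("OPC patterns: CSR counts, focus containment, mask fraction, errors", {
  # no foci: homogeneous Poisson; count within 4 sqrt(lambda A) of lambda A
  p <- generate_opc_pattern(1, 300, seed = 3)
  expect_lt(abs(nrow(p$points) - 300), 4 * sqrt(300))
  expect_false(any(p$points$in_focus))
  expect_equal(focus_area_fraction(p), 0)

  # one focus, zero background: every point inside the footprint
  f <- list(list(center = c(0.5, 0.5), radius = 0.15, density = 400))
  p1 <- generate_opc_pattern(1, 0, f, seed = 4)
  expect_gt(nrow(p1$points), 0)
  expect_true(all(p1$points$in_focus))
  expect_true(all((p1$points$x - 0.5)^2 + (p1$points$y - 0.5)^2 <= 0.15^2))

  # mask area fraction vs independent fine-grid integration (overlapping foci)
  f2 <- list(list(center = c(0.35, 0.5), radius = 0.2, density = 500),
             list(center = c(0.6, 0.5), radius = 0.15, density = 500))
  p2 <- generate_opc_pattern(1, 100, f2, seed = 5)
  g <- (seq_len(2000) - 0.5) / 2000
  xx <- rep(g, times = 2000); yy <- rep(g, each = 2000)
  oracle <- mean((xx - 0.35)^2 + (yy - 0.5)^2 <= 0.2^2 |
                 (xx - 0.6)^2 + (yy - 0.5)^2 <= 0.15^2)
  expect_equal(focus_area_fraction(p2), oracle, tolerance = 1e-3)

  expect_error(generate_opc_pattern(1, 100, list(
    list(center = c(0.05, 0.5), radius = 0.2, density = 500)), seed = 1),
    "outside the region")
  expect_error(generate_opc_pattern(1, 100, list(
    list(center = c(0.5, 0.5), radius = 0.2, density = 50)), seed = 1),
    "must exceed")
  expect_identical(generate_opc_pattern(1, 200, f2, seed = 9)$points,
                   generate_opc_pattern(1, 200, f2, seed = 9)$points)
})
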