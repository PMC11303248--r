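# Two-group cohort simulation: per-animal learning-curve parameters, optional
# full telemetry sessions, and a latent-deficit -> hyperdensity-coverage link.

#' Default two-group effect specification
#'
#' The impaired group's plateau velocity is reduced by `deficit` and its
#' learning length constant is rescaled so the initial learning slope
#' `(v_max - v0) / lambda` matches the control group's: both groups start
#' and learn identically, but the impaired group plateaus lower, so the
#' curves separate only once the controls pull ahead at later distances.
#'
#' @param deficit Fractional reduction of the impaired group's `v_max`.
#' @return Named list of per-group multipliers of `(v_max, lambda_learn)`;
#'   `lambda_mult = "match_slope"` is resolved against the base parameters.
#' @export
group_effects_default <- function(deficit = 0.15) {
  list(control = list(v_max_mult = 1, lambda_mult = 1),
       impaired = list(v_max_mult = 1 - deficit, lambda_mult = "match_slope"))
}

#' Default latent-deficit to coverage link
#'
#' Percent hyperdensity coverage is a logistic function of the animal's
#' latent plateau deficit (1 - v_max_i / v_max_base) with Gaussian noise on
#' the logit scale: strictly monotone increasing in the deficit, bounded in
#' (0, 100).
#'
#' @param logit_intercept,logit_slope Link coefficients.
#' @param logit_noise_sd Noise sd on the logit scale; 0 gives a deterministic
#'   monotone link.
#' @return A `coverage_model` list.
#' @export
coverage_model_default <- function(logit_intercept = -2.5, logit_slope = 8,
                                   logit_noise_sd = 0.4) {
  list(logit_intercept = logit_intercept, logit_slope = logit_slope,
       logit_noise_sd = logit_noise_sd)
}

resolve_lambda_mult <- function(eff, base) {
  if (identical(eff$lambda_mult, "match_slope")) {
    vm <- base$v_max * eff$v_max_mult
    (vm - base$v0) / (base$v_max - base$v0)
  } else eff$lambda_mult
}

#' Simulate a two-group complex-wheel cohort
#'
#' Each animal receives a per-animal plateau velocity
#' `v_max_i = v_max_g * (1 + cv_between * z_i)` and its group's learning
#' length constant; its latent deficit `1 - v_max_i / v_max_base` is mapped
#' to percent hyperdensity coverage through `coverage_model`. At
#' `level = "curve"` the per-animal milestone velocities are the closed-form
#' curve [learning_velocity()] evaluated at each bin midpoint plus
#' independent milestone jitter (emulating the residual scatter of binned
#' pipeline estimates). At `level = "events"` each animal additionally gets a
#' full simulated telemetry session via [simulate_session()].
#'
#' @param n_per_group Animals per group (>= 2).
#' @param group_effects Named list of per-group `(v_max_mult, lambda_mult)`;
#'   see [group_effects_default()].
#' @param wheel A [make_wheel()] geometry (used at `level = "events"`).
#' @param base_behavior Baseline [behavior_params()].
#' @param coverage_model See [coverage_model_default()].
#' @param seed Master integer seed; animal-level draws use the `"cohort"`
#'   substream and each session gets a derived per-animal seed.
#' @param level `"curve"` (closed-form milestone velocities) or `"events"`
#'   (full telemetry sessions).
#' @param milestones_km Milestone grid for `level = "curve"`; velocities are
#'   evaluated at `milestone - bin_width/2` (the bin midpoint implied by the
#'   grid spacing).
#' @param cv_between Between-animal coefficient of variation of `v_max`.
#' @param milestone_noise_sd Sd (m/min) of independent per-milestone jitter
#'   at `level = "curve"`.
#' @return List with `meta` (per animal: `animal_id`, `group`, `v_max`,
#'   `lambda_learn`, `deficit`, `coverage_percent`), `curves` (long data
#'   frame `animal_id`, `group`, `milestone_km`, `velocity`; `NULL` until
#'   computed for `level = "events"`) and, at `level = "events"`, `sessions`
#'   (named list of [simulate_session()] results).
#' @export
simulate_cohort <- function(n_per_group = 10,
                            group_effects = group_effects_default(),
                            wheel = NULL,
                            base_behavior = behavior_params(),
                            coverage_model = coverage_model_default(),
                            seed = 1L,
                            level = c("curve", "events"),
                            milestones_km = seq(0.5, 7, 0.5),
                            cv_between = 0.10,
                            milestone_noise_sd = 0.5) {
  level <- match.arg(level)
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  stopifnot(inherits(base_behavior, "behavior_params"))
  groups <- names(group_effects)
  if (length(groups) < 2) stop("group_effects must name at least two groups")
  if (level == "events") validate_wheel(wheel)

  meta <- with_seed(substream_seed(seed, "cohort"), {
    rows <- lapply(groups, function(g) {
      eff <- group_effects[[g]]
      vm_g <- base_behavior$v_max * eff$v_max_mult
      lam_g <- base_behavior$lambda_learn * resolve_lambda_mult(eff, base_behavior)
      vmax_i <- pmax(vm_g * (1 + cv_between * stats::rnorm(n_per_group)),
                     base_behavior$v0 * 1.05)
      data.frame(animal_id = sprintf("%s_%02d", g, seq_len(n_per_group)),
                 group = g, v_max = vmax_i, lambda_learn = lam_g)
    })
    m <- do.call(rbind, rows)
    m$deficit <- 1 - m$v_max / base_behavior$v_max
    lp <- coverage_model$logit_intercept +
      coverage_model$logit_slope * m$deficit +
      stats::rnorm(nrow(m), 0, coverage_model$logit_noise_sd)
    m$coverage_percent <- 100 * stats::plogis(lp)
    m
  })

  if (level == "curve") {
    width <- diff(milestones_km)
    width <- if (length(width)) c(width[1], width) else 0.5
    mids <- milestones_km - width / 2
    curves <- with_seed(substream_seed(seed, "noise"), {
      do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
        v <- learning_velocity(mids, base_behavior$v0, meta$v_max[i],
                               meta$lambda_learn[i]) +
          stats::rnorm(length(mids), 0, milestone_noise_sd)
        data.frame(animal_id = meta$animal_id[i], group = meta$group[i],
                   milestone_km = milestones_km, velocity = v)
      }))
    })
    return(list(meta = meta, curves = curves, sessions = NULL))
  }

  sessions <- lapply(seq_len(nrow(meta)), function(i) {
    beh <- base_behavior
    beh$v_max <- meta$v_max[i]
    beh$lambda_learn <- meta$lambda_learn[i]
    simulate_session(beh, wheel,
                     seed = substream_seed(seed, "cohort") + 17L * i)
  })
  names(sessions) <- meta$animal_id
  list(meta = meta, curves = NULL, sessions = sessions)
}

#' Learning curves for every animal of an event-level cohort
#'
#' Runs [session_pipeline()] on each simulated session and stacks the binned
#' curves.
#'
#' @param cohort A [simulate_cohort()] result with `level = "events"`.
#' @param wheel The wheel geometry the cohort ran on.
#' @param bin_edges_km Distance bin edges, km.
#' @return Long data frame `animal_id`, `group`, `milestone_km`, `velocity`.
#' @export
cohort_learning_curves <- function(cohort, wheel,
                                   bin_edges_km = seq(0, 7, 0.5)) {
  stopifnot(!is.null(cohort$sessions))
  do.call(rbind, lapply(seq_len(nrow(cohort$meta)), function(i) {
    res <- session_pipeline(cohort$sessions[[i]]$intercepts, wheel,
                            bin_edges_km,
                            animal_id = cohort$meta$animal_id[i],
                            group = cohort$meta$group[i])
    res$curve[, c("animal_id", "group", "milestone_km", "velocity")]
  }))
}
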