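# Monte-Carlo operating characteristics of the milestone comparison and the
# coverage regression, run on curve-level synthetic cohorts.

#' Power of the late-milestone group comparison
#'
#' Simulates replicate two-group cohorts with an impaired-group plateau
#' deficit and records, per milestone, how often the Bonferroni-adjusted
#' per-milestone contrast (over the tested milestones) rejects at 0.05.
#'
#' @param n_rep Number of replicate cohorts.
#' @param n_per_group Animals per group.
#' @param deficit Fractional plateau deficit of the impaired group.
#' @param milestones Milestones tested (the Bonferroni family).
#' @param base_behavior Baseline [behavior_params()].
#' @param cv_between Between-animal CV of `v_max`.
#' @param milestone_noise_sd Per-milestone jitter sd, m/min.
#' @param method Passed to [compare_learning_curves()].
#' @param seed Master seed; replicate r uses `seed + r`.
#' @return List: `reject_rate` (named by milestone), `reject_all` (fraction
#'   of replicates rejecting at every tested milestone), `n_rep`.
#' @export
milestone_power_study <- function(n_rep = 200, n_per_group = 10,
                                  deficit = 0.15,
                                  milestones = c(6.5, 7),
                                  base_behavior = behavior_params(),
                                  cv_between = 0.10,
                                  milestone_noise_sd = 0.5,
                                  method = "two_way_anova_bonferroni",
                                  seed = 1L) {
  rej <- matrix(NA, n_rep, length(milestones))
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(n_per_group,
                          group_effects_default(deficit),
                          base_behavior = base_behavior,
                          seed = seed + r, level = "curve",
                          milestones_km = milestones,
                          cv_between = cv_between,
                          milestone_noise_sd = milestone_noise_sd)
    res <- compare_learning_curves(co$curves, milestones, method)
    rej[r, match(res$milestone_km, milestones)] <- res$p_adjusted < 0.05
  }
  rates <- colMeans(rej)
  names(rates) <- as.character(milestones)
  list(reject_rate = rates, reject_all = mean(apply(rej, 1, all)),
       n_rep = n_rep)
}

#' Family-wise false-positive rate with no group effect
#'
#' Simulates replicate cohorts with identical group parameters and records
#' how often any Bonferroni-adjusted milestone contrast rejects at 0.05.
#'
#' @inheritParams milestone_power_study
#' @return List: `familywise_rate`, `per_milestone_rate`, `n_rep`.
#' @export
milestone_type1_study <- function(n_rep = 500, n_per_group = 10,
                                  milestones = seq(0.5, 7, 0.5),
                                  base_behavior = behavior_params(),
                                  cv_between = 0.10,
                                  milestone_noise_sd = 0.5,
                                  method = "two_way_anova_bonferroni",
                                  seed = 1L) {
  effects <- list(control = list(v_max_mult = 1, lambda_mult = 1),
                  impaired = list(v_max_mult = 1, lambda_mult = 1))
  any_rej <- logical(n_rep)
  per <- matrix(NA, n_rep, length(milestones))
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(n_per_group, effects,
                          base_behavior = base_behavior,
                          seed = seed + r, level = "curve",
                          milestones_km = milestones,
                          cv_between = cv_between,
                          milestone_noise_sd = milestone_noise_sd)
    res <- compare_learning_curves(co$curves, milestones, method)
    rej <- res$p_adjusted < 0.05
    per[r, match(res$milestone_km, milestones)] <- rej
    any_rej[r] <- any(rej)
  }
  rates <- colMeans(per)
  names(rates) <- as.character(milestones)
  list(familywise_rate = mean(any_rej), per_milestone_rate = rates,
       n_rep = n_rep)
}

#' Sign stability of the coverage-velocity slope across cohorts
#'
#' Simulates replicate cohorts with the default impaired-group deficit and
#' latent-deficit coverage link, regresses milestone velocity on coverage
#' (both groups pooled), and records the fraction of replicates with a
#' negative fitted slope at each milestone.
#'
#' @inheritParams milestone_power_study
#' @param coverage_model See [coverage_model_default()].
#' @return List: `negative_slope_fraction` (named by milestone),
#'   `mean_r_squared`, `n_rep`.
#' @export
coverage_slope_study <- function(n_rep = 200, n_per_group = 10,
                                 deficit = 0.15,
                                 milestones = c(6.5, 7),
                                 base_behavior = behavior_params(),
                                 coverage_model = coverage_model_default(),
                                 cv_between = 0.10,
                                 milestone_noise_sd = 0.5,
                                 seed = 1L) {
  neg <- matrix(NA, n_rep, length(milestones))
  r2 <- matrix(NA, n_rep, length(milestones))
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(n_per_group,
                          group_effects_default(deficit),
                          base_behavior = base_behavior,
                          coverage_model = coverage_model,
                          seed = seed + r, level = "curve",
                          milestones_km = milestones,
                          cv_between = cv_between,
                          milestone_noise_sd = milestone_noise_sd)
    for (j in seq_along(milestones)) {
      cv <- co$curves[co$curves$milestone_km == milestones[j], ]
      cv <- cv[match(co$meta$animal_id, cv$animal_id), ]
      reg <- coverage_regression(co$meta$coverage_percent, cv$velocity)
      neg[r, j] <- reg$slope < 0
      r2[r, j] <- reg$r_squared
    }
  }
  fr <- colMeans(neg)
  names(fr) <- as.character(milestones)
  list(negative_slope_fraction = fr, mean_r_squared = colMeans(r2),
       n_rep = n_rep)
}
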