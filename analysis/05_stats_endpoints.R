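#!/usr/bin/env Rscript
# Step 5 — statistical endpoints.
#
# (a) Milestone comparison: two-way ANOVA (group x milestone) contrasts at
#     6.5 and 7 km with Bonferroni adjustment over the tested milestones.
# (b) Coverage regression: per-animal velocity at 6.5 km against percent
#     hyperdensity coverage, pooled across groups.
# (c) Operating characteristics: power at the late milestones, family-wise
#     false-positive rate across all 14 milestones, and the sign stability
#     of the coverage slope, each over seeded replicate cohorts.

library(complexwheel)

MASTER_SEED <- 101
dir.create("results", showWarnings = FALSE)

wheel <- make_wheel(22, 0.38, "complex", seed = 1)
behavior <- behavior_params(session_duration = 10 * 24 * 3600)
cohort <- simulate_cohort(8, wheel = wheel, base_behavior = behavior,
                          seed = MASTER_SEED, level = "events")
curves <- cohort_learning_curves(cohort, wheel)

cmp <- compare_learning_curves(curves, c(6.5, 7),
                               "two_way_anova_bonferroni")
write.csv(cmp, "results/milestone_comparison.csv", row.names = FALSE)
cat("Milestone contrasts (two-way ANOVA + Bonferroni):\n")
print(cmp[, c("milestone_km", "mean_a", "mean_b", "statistic", "df",
              "p_raw", "p_adjusted")], row.names = FALSE, digits = 4)

v65 <- curves[curves$milestone_km == 6.5, ]
v65 <- v65[match(cohort$meta$animal_id, v65$animal_id), "velocity"]
ok <- !is.na(v65)
reg <- coverage_regression(cohort$meta$coverage_percent[ok], v65[ok])
cat("\nCoverage vs velocity at 6.5 km: ")
print(reg)
jsonlite::write_json(unclass(reg), "results/coverage_regression.json",
                     auto_unbox = TRUE, digits = NA)

ps <- milestone_power_study(n_rep = 200, seed = MASTER_SEED)
t1 <- milestone_type1_study(n_rep = 500, seed = MASTER_SEED)
st <- coverage_slope_study(n_rep = 200, seed = MASTER_SEED)
oc <- data.frame(
  quantity = c("power_6.5km", "power_7km", "familywise_false_positive",
               "negative_slope_fraction_6.5km", "negative_slope_fraction_7km"),
  value = c(ps$reject_rate[["6.5"]], ps$reject_rate[["7"]],
            t1$familywise_rate, st$negative_slope_fraction[["6.5"]],
            st$negative_slope_fraction[["7"]]),
  n_replicates = c(200, 200, 500, 200, 200))
write.csv(oc, "results/operating_characteristics.csv", row.names = FALSE)
cat("\nOperating characteristics over replicate cohorts:\n")
print(oc, row.names = FALSE)
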