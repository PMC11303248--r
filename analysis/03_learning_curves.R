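#!/usr/bin/env Rscript
# Step 3 — distance-binned learning curves for the cohort.
#
# Runs the full pipeline (2-s segmentation -> revolutions -> sliding-window
# speed -> 100-revolution smoothing -> 0.5-km distance bins) on every
# animal's ground-truth event stream and writes the long curve table plus a
# group-mean summary. Comparisons are distance-based, so animals appear at a
# milestone only once they have traveled that far.

library(complexwheel)

MASTER_SEED <- 101
dir.create("results", showWarnings = FALSE)

wheel <- make_wheel(22, 0.38, "complex", seed = 1)
behavior <- behavior_params(session_duration = 10 * 24 * 3600)
cohort <- simulate_cohort(8, wheel = wheel, base_behavior = behavior,
                          seed = MASTER_SEED, level = "events")

curves <- cohort_learning_curves(cohort, wheel, bin_edges_km = seq(0, 7, 0.5))
write_curve_csv(curves, "results/learning_curves.csv")

summ <- aggregate(velocity ~ group + milestone_km, curves,
                  function(v) c(mean = mean(v), sd = sd(v), n = sum(!is.na(v))))
summ <- do.call(data.frame, summ)
names(summ) <- c("group", "milestone_km", "mean_velocity", "sd_velocity", "n")
write.csv(summ, "results/learning_curves_group_summary.csv", row.names = FALSE)

wide <- reshape(summ[, c("group", "milestone_km", "mean_velocity")],
                idvar = "milestone_km", timevar = "group",
                direction = "wide")
wide$delta <- wide$mean_velocity.control - wide$mean_velocity.impaired
cat("Group separation (control - impaired, m/min) by milestone:\n")
print(wide, row.names = FALSE, digits = 3)
cat(sprintf("\nEarly (<=1.5 km) mean separation %.2f m/min vs late (>=6.5 km) %.2f m/min:\n",
            mean(wide$delta[wide$milestone_km <= 1.5]),
            mean(wide$delta[wide$milestone_km >= 6.5], na.rm = TRUE)))
cat("the groups separate only once controls approach their higher plateau.\n")
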