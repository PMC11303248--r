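# Group comparisons at distance milestones and the coverage-vs-performance
# regression.

#' Compare two groups' learning curves at distance milestones
#'
#' Two methods are provided. `"two_way_anova_bonferroni"` fits an ordinary
#' two-factor model (group x milestone, animals as replicates) and reports
#' per-milestone group contrasts using the pooled residual mean square, with
#' Bonferroni adjustment over the tested milestones — the multiple-comparison
#' style that accompanies two-way ANOVA in common figure annotations.
#' `"welch_per_milestone_bonferroni"` runs an unpaired two-sided Welch t-test
#' at each milestone, again Bonferroni-adjusted over the tested milestones.
#' In both cases `p_adjusted = min(1, p_raw * n_milestones)`.
#'
#' Animals missing a milestone (they never reached that distance) are dropped
#' from that milestone only, with a note; a milestone with fewer than two
#' animals in either group is dropped entirely.
#'
#' @param curves Long data frame `animal_id`, `group`, `milestone_km`,
#'   `velocity` with exactly two groups.
#' @param milestones Milestones (km) to test; the Bonferroni family.
#' @param method Comparison method, see above.
#' @return Data frame with one row per tested milestone: `milestone_km`,
#'   `group_a`, `group_b`, `mean_a`, `mean_b`, `n_a`, `n_b`, `statistic`,
#'   `df`, `p_raw`, `p_adjusted`, `method`.
#' @export
compare_learning_curves <- function(curves,
                                    milestones = c(6.5, 7),
                                    method = c("two_way_anova_bonferroni",
                                               "welch_per_milestone_bonferroni")) {
  method <- match.arg(method)
  groups <- sort(unique(as.character(curves$group)))
  if (length(groups) != 2) stop("exactly two groups are required")
  cc <- curves[curves$milestone_km %in% milestones & !is.na(curves$velocity), ]
  if (!nrow(cc)) stop("no observations at the requested milestones")
  for (g in groups)
    if (!any(cc$group == g))
      stop(sprintf("group '%s' has no data at any tested milestone", g))

  dropped <- sum(is.na(curves$velocity[curves$milestone_km %in% milestones]))
  if (dropped > 0)
    message(sprintf("note: %d animal-milestone value(s) missing and dropped pairwise",
                    dropped))

  keep <- vapply(milestones, function(m) {
    sub <- cc[cc$milestone_km == m, ]
    all(table(factor(sub$group, levels = groups)) >= 2)
  }, logical(1))
  if (!all(keep))
    message(sprintf("note: %d milestone(s) dropped (fewer than 2 animals in a group)",
                    sum(!keep)))
  milestones <- milestones[keep]
  if (!length(milestones)) stop("no testable milestones remain")
  m_tests <- length(milestones)
  cc <- cc[cc$milestone_km %in% milestones, ]

  if (method == "two_way_anova_bonferroni") {
    # a single tested milestone degenerates to the one-factor model
    form <- if (length(unique(cc$milestone_km)) > 1)
      velocity ~ group * factor(milestone_km) else velocity ~ group
    fit <- stats::aov(form, data = cc)
    mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
    df_err <- stats::df.residual(fit)
  }

  rows <- lapply(milestones, function(m) {
    sub <- cc[cc$milestone_km == m, ]
    va <- sub$velocity[sub$group == groups[1]]
    vb <- sub$velocity[sub$group == groups[2]]
    if (method == "welch_per_milestone_bonferroni") {
      tt <- stats::t.test(va, vb, var.equal = FALSE)
      stat <- unname(tt$statistic); df <- unname(tt$parameter)
      p <- tt$p.value
    } else {
      se <- sqrt(mse * (1 / length(va) + 1 / length(vb)))
      stat <- (mean(va) - mean(vb)) / se
      df <- df_err
      p <- 2 * stats::pt(-abs(stat), df)
    }
    data.frame(milestone_km = m, group_a = groups[1], group_b = groups[2],
               mean_a = mean(va), mean_b = mean(vb),
               n_a = length(va), n_b = length(vb),
               statistic = stat, df = df, p_raw = p,
               p_adjusted = min(1, p * m_tests), method = method)
  })
  do.call(rbind, rows)
}

#' Regress milestone velocity on percent hyperdensity coverage
#'
#' Ordinary least squares of end-of-test velocity on percent area covered by
#' focal OPC hyperdensities, summarising the coverage-vs-motor-performance
#' association by slope, intercept and R^2.
#'
#' @param coverage_percent Per-animal coverage, percent.
#' @param velocity Per-animal velocity at the milestone, m/min.
#' @return List of class `coverage_regression`: `slope` (m/min per percent),
#'   `intercept` (m/min), `r_squared`, `n`, `degenerate` (`TRUE` when the
#'   response is constant, in which case `r_squared` is reported as 0).
#' @export
coverage_regression <- function(coverage_percent, velocity) {
  ok <- is.finite(coverage_percent) & is.finite(velocity)
  x <- coverage_percent[ok]; y <- velocity[ok]
  if (length(x) < 3) stop("at least 3 paired observations are required")
  if (stats::sd(x) == 0) stop("constant predictor: slope undefined")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  degenerate <- ss_tot == 0
  r2 <- if (degenerate) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(x), degenerate = degenerate),
            class = "coverage_regression")
}

#' @export
print.coverage_regression <- function(x, ...) {
  cat(sprintf("<coverage_regression> slope = %.4f m/min per %%, intercept = %.3f, R^2 = %.4f, n = %d%s\n",
              x$slope, x$intercept, x$r_squared, x$n,
              if (x$degenerate) " (degenerate fit)" else ""))
  invisible(x)
}
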