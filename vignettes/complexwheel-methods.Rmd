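---
title: "From wheel telemetry to motor-learning curves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wheel telemetry to motor-learning curves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexwheel)
```

## The measurement problem

A complex running wheel has irregularly spaced rungs, so a mouse cannot fall
into a stereotyped gait: sustaining speed requires learning the rung
pattern. Motor learning is therefore read out as running velocity as a
function of *cumulative distance*, not time — two animals are compared once
each has traveled the same distance, which removes differences in how much
they choose to run.

The raw measurement is the analog output of an infrared sensor aimed at the
rung path: each rung passage produces one pulse ("rung intercept"). This
package implements the full chain from that trace to group-level endpoints,
plus a ground-truthed generator for every input, so that each stage is
testable without any recorded animal data.

## Processing chain and its conventions

1. **Peak detection** (`detect_intercepts`). Local maxima above
   `median + k * MAD` (raw MAD, `k = 6` by default, about four Gaussian
   sigma), separated by a refractory period (default 20 ms, about four
   pulse widths). Robust location/scale make the threshold insensitive to
   pulse density. Candidates are accepted tallest-first, so of two peaks
   within one refractory period the larger wins. The event time is the
   peak-sample time.
2. **Active-period segmentation** (`segment_active`). Running bouts are
   maximal runs of intercepts with consecutive gaps strictly under 2 s. The
   boundary is strict: a gap of exactly 2.000 s splits bouts. Singleton
   events form singleton bouts (they carry distance even though they yield
   no speed estimate).
3. **Revolution reconstruction** (`count_revolutions`). One revolution per
   `n_rungs` filtered intercepts; the k-th revolution completes at filtered
   intercept `k * n_rungs`. Because the wheel's phase is physically
   continuous, the counter persists across bout boundaries by default;
   `reset_per_bout = TRUE` is provided for sensitivity analyses. The
   partial revolution at the end of a record is discarded: distance counts
   complete revolutions only, `distance = revolutions x circumference`.
4. **Sliding-window speed** (`sliding_speed`). A window is `n_rungs + 1`
   consecutive intercepts — by construction exactly one circumference of
   rotation, whatever the rung spacing — and speed is
   `circumference / elapsed time`, reported in m/min. Windows never span a
   bout boundary. Each window is stamped at its end time (a `midpoint`
   option exists); its cumulative distance is the event-resolved
   `(filtered index / n_rungs) x circumference`.
5. **Smoothing** (`smooth_speed`). Centered moving average over all entries
   within half a window (default 100 revolutions) of the current entry's
   revolution index, shrinking symmetrically at record edges (minimum one
   entry). Centered was chosen over trailing to avoid a systematic phase
   lag of the learning curve; the difference is invisible at the 0.5-km
   bin scale (the 100-revolution window is only 38 m of travel).
6. **Distance binning** (`bin_velocity_by_distance`). Half-open bins
   `[lo, hi)` of cumulative distance, default 0.5-km edges from 0 to 7 km;
   the bin value is the unweighted mean of the smoothed window estimates in
   the bin, labeled by the bin's upper edge (the "milestone"). Bins beyond
   an animal's final distance are missing; a reached-but-empty bin is
   missing with a warning. The 0.5-km default matches endpoints quoted at
   6.5 and 7 km; both the width and a time-weighted bin mean are
   configurable.

Velocities are reported in m/min throughout: mouse wheel speeds then fall
in a readable 5–30 range.

## The synthetic behavior model

Sessions are a renewal process of running bouts: exponential inter-bout
gaps (rate `bout_rate`, default 1.5 h⁻¹) and lognormal bout durations
(default median 70 s, log-sd 0.7). Within a bout the animal tracks a target
velocity that depends only on cumulative distance,

    v(d) = v0 + (v_max - v0) * (1 - exp(-d / lambda)),

with `v0 = 5` m/min, `v_max = 25` m/min and learning length constant
`lambda = 1.4` km by default, multiplied by stationary lognormal AR(1)
noise with coefficient of variation `within_bout_cv` (default 0.1,
autocorrelation 0.9). With these defaults an animal accumulates roughly
1 km per day — a realistic complex-wheel workload that passes the 7-km
test distance within one to two weeks.

The simulator is event-driven: between consecutive rung crossings the
angular velocity is constant, and crossing times are exact solutions of the
angle equation, not a discretization. Crossing angles are computed by
index arithmetic on the rung lattice (never accumulated), so multi-day
sessions with ~10⁶ events carry no floating drift, and ground-truth
distance is exactly `revolutions x circumference`. Rotation is
forward-only; the physical sensor cannot distinguish direction, and
reversal modeling is out of scope. Bouts end at their last crossing
(residual partial rotation within a bout's final fraction of a rung gap is
dropped), which keeps every inter-crossing segment inside one bout.

The sensor model renders one Gaussian pulse (sd 5 ms, amplitude 1 ± 10%)
per non-missed intercept at 1 kHz on Gaussian baseline noise (sd 0.02,
i.e. a strong-reflectance infrared sensor), with 1% pulse dropout and ~0.01
spurious pulses per second. Dropout and spurious pulses are bookkept so
detection can be scored against the pulses actually present.

## Cohort design and calibration

`simulate_cohort` draws two groups. The impaired group's plateau `v_max`
is reduced 15% and its `lambda` is rescaled so the *initial learning
slope* `(v_max - v0)/lambda` matches the control group's: both groups are
indistinguishable early and separate only as controls approach their
higher plateau — the qualitative signature of a late-emerging motor
deficit. Per-animal plateaus vary with a 10% between-animal CV, and
curve-level milestone values carry 0.5 m/min of independent jitter
(emulating the residual scatter of binned pipeline estimates). Under these
conditions the late-milestone standardized effect is ~1.5 sd, which is what
makes a two-group comparison at n = 8–10 per group marginally but reliably
detectable — the regime the study design occupies.

Each animal's latent deficit `1 - v_max_i / v_max_base` maps to percent
hyperdensity coverage through a logistic link on the logit scale
(intercept −2.5, slope 8, noise sd 0.4): strictly monotone, bounded in
(0, 100), giving control animals ~5–15% coverage and impaired animals
~20–60%. The link is a phenomenological stand-in for the biological claim
that focal OPC hyperdensity burden and motor impairment share a cause; it
makes the sign and rough strength of the coverage–velocity association a
known ground truth.

Monte-Carlo operating characteristics (power at 6.5/7 km, family-wise
false-positive rate over fourteen 0.5-km milestones, coverage-slope sign
stability) are computed on curve-level cohorts: the closed-form curve
family plus the noise model above, 200 replicates for power and slope
stability, 500 for the null. Event-level telemetry is deliberately not
re-simulated per replicate — one full cohort is ~9 million events — and its
fidelity is established separately: distance conservation is exact,
constant-rotation speed recovery is exact to 1e-9 (2% from rendered
traces), and a full event-level cohort (8 per group, 10-day sessions, run
once) reproduces the late-only separation and the negative coverage slope
end to end. Event-level cohort sessions default to 10 days here because the
comparison is distance-based: sessions must be long enough for essentially
every animal, including impaired ones, to pass 7 km.

## Histology quantification

ROIs are classified purely by Pdgfra⁺ cell count: fewer than four cells is
non-hyperdensity, more than six is hyperdensity, and four to six is
indeterminate. Indeterminate ROIs enter the denominator (total area) but
neither class — the rule's gap is deliberate, and collapsing it either way
would manufacture certainty the count does not carry. Coverage percent is
`100 x hyperdense area / region area`, computed from square ROI tiles laid
on a grid (side length configurable; the enrichment analyses calibrate the
tile so the expected background count is ~2 cells). The synthetic point
pattern (homogeneous Poisson background plus Poisson discs) retains its
focus footprints as a truth mask; its area fraction is analytic for
disjoint foci and grid-integrated when foci overlap. Tile-based coverage
systematically underestimates small footprints (edge tiles straddle the
focus boundary and dilute counts); tests bound this error at one
percentage point when the tile is at most a quarter of the focus radius.
The g-ratio is the axonal short-axis diameter divided by the whole-fiber
diameter in the same axis, with `fiber < axon` rejected as a mis-measured
pair.

## Statistical endpoints

`compare_learning_curves` offers the two families used for behavioral
endpoints. The default fits an ordinary two-factor model (group x
milestone, animals as replicates) and reports per-milestone group
contrasts on the pooled residual mean square, Bonferroni-adjusted over the
tested milestones (`p_adj = min(1, p x m)` exactly); the alternative runs
Welch t-tests per milestone with the same adjustment, and is also the
recommended route for badly unbalanced data, since the pooled-MSE contrast
assumes comparable cell variances. All tests are two-sided. The Bonferroni
family is the set of milestones actually tested in one comparison — the
late-milestone endpoint tests {6.5, 7} km, while the null calibration
spans all fourteen 0.5-km milestones. Two caveats are documented rather
than hidden: the ordinary two-factor layout treats an animal's repeated
milestones as independent replicates (as common figure-annotation software
does), which the null simulation shows is conservative here
(family-wise rate ~0.03 against the 0.05 nominal); and milestones where a
group has fewer than two animals are dropped with a note.

`coverage_regression` is ordinary least squares of milestone velocity on
coverage percent with `R² = 1 - SS_res / SS_tot`; a constant predictor is
an error, and a constant response is reported as `R² = 0` with a
degenerate-fit flag rather than `NaN`. The regression pools both genotype
groups: the latent-deficit link makes coverage informative within and
between groups, and pooling mirrors reading a single scatter of animals
against their coverage.

## Numerical choices and degenerate inputs

- Exactly-2.0-s gaps split bouts (strict inequality); distance bins are
  half-open `[lo, hi)`, so a value on an edge belongs to the upper bin.
- Zero elapsed time inside a speed window (duplicate timestamps) is an
  error, not an infinite speed.
- An all-constant trace yields an empty event series, not an error; a
  refractory period shorter than one sample is a configuration error.
- Smoothing uses a cumulative-sum window mean with `findInterval`
  boundaries; tests pin it to the O(n·w) direct mean at 1e-12 relative.
- One master seed fans out to named substreams (bouts, noise, sensor,
  foci, cohort), so regenerating any one component never perturbs the
  others; identical seeds give bit-identical outputs.

## What the generator does not emulate

No circadian structure (bouts are a homogeneous renewal process), no
within-bout fatigue, no direction reversals or wheel recoil, no
inter-animal interference, and no real logger artifacts (clock drift,
quantization, chunked writes). The OPC patterns are Poisson — no cell-cell
inhibition or clustering beyond the imposed foci — and coverage enters
through an invented link, so passing tests demonstrate that the pipeline
and statistics behave correctly under the stated model, not that the model
is a complete account of mouse behavior or OPC biology. The milestone
problem sizes, replicate counts and session lengths quoted above are the
package's standing choices and are the ones its tests and reproduction
script run at.
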