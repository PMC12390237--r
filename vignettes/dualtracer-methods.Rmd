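---
title: "Methods: dual-tracer accounting, simulation and apportionment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-tracer accounting, simulation and apportionment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualtracer)
```

## The model

A dual-tracer exposure experiment labels the two uptake routes of a metal
with two stable isotopes of that metal: one spiked into the water, one bound
to the food. Because the isotopes are chemically identical but
mass-resolvable by ICP-MS, a single animal yields an independent
concentration for each route.

`dualtracer` assumes the simplest kinetic model consistent with a short
(weeks-long) exposure of a tolerant animal:

* **Linear accumulation.** Tissue tracer concentration in group $g$ at day
  $t$ is $C(t) = C_{bg} + J_{in,g}\, t$, with $J_{in}$ constant per group
  and route (μg g⁻¹ d⁻¹). No elimination, no saturation, no growth
  dilution. These are assumptions of the *accounting*, not facts about the
  animal; they are appropriate when accumulation plots are close to straight
  lines and growth does not differ between groups (which
  `compare_growth()` checks).
* **Constant background.** Control animals carry each tracer at its natural
  share of the ambient metal burden, constant over the experiment. The
  background estimate is the control-group mean, pooled over sampling days
  by default. A `time_matched = TRUE` option subtracts the same-day control
  mean instead; pooled is the default because it has lower variance and
  because a trend-free control makes the two equivalent in expectation.
  Neither option is "the" correct one — the choice only matters if the
  control drifts, which the per-day means retained in the
  `background_estimate` object let the analyst check.
* **Feeding-window scaling.** Animals that filter-feed continuously ingest
  labelled food only while it is offered ($h$ hours per day). Dietary
  measurements are multiplied by $S = 24/h$ (here $S = 8$ for a 3-hour
  window) to express dietary influx on a per-day basis. By linearity,
  scaling before or after background subtraction is identical; the package
  subtracts first and this identity is unit-tested.
* **Multiplicative measurement noise.** Measured concentrations are the
  model value times a positive, mean-1 noise factor. This mimics
  ICP-MS-type relative error and guarantees positive concentrations.

Influx rates are estimated by ordinary least squares of per-animal new
accumulation on exposure day, per group and tracer. Relative importance of
the waterborne route in a group × day cell is
$f_w = 100\,\bar{\Delta C}_w / (\bar{\Delta C}_w + \bar{\Delta C}_d)$,
summarized over the treatment cells.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `feeding_hours_per_day` | h | 3 | typical ration window for mussels; sets $S = 8$ |
| `noise_cv` | fraction | 0.10 | typical overall CV of replicated ICP-MS tissue determinations; the source study reports only QC deviations "< 10%", so this is a free, documented parameter |
| `noise_law` | — | lognormal | strictly positive, multiplicative; `truncnorm` alternative behind a flag |
| `tank_cv` | fraction | 0 | tanks treated as labels (replicates) by default; a tank-level multiplicative effect is available for robustness studies |
| `regression_through_origin` | flag | FALSE | background subtraction should already leave a near-zero intercept; forcing the origin is an untestable assumption. The free intercept doubles as a diagnostic: a large fitted intercept flags a failure of background subtraction |
| `qc_tolerance` | fraction | 0.10 | spike-recovery acceptance threshold |
| `bootstrap_reps` | count | 0 (off) | percentile bootstrap for the mean waterborne share; ≥ 100 enforced when enabled |

## The default scenario

`anodonta_scenario()` encodes a concrete 30-day mussel experiment: four
groups (control + three levels), waterborne tracer at 2.5 / 5.3 / 10.8
μg L⁻¹ with dietary tracer at 1.9 / 3.7 / 6.2 μg g⁻¹ dw, 3 tanks × 15
animals per group, 6 animals per group sampled on days 10, 20 and 30,
backgrounds 1.52 / 0.87 μg g⁻¹ dw.

The true influx rates deserve a note, because the study this scenario
emulates published only per-route summaries (mean ± SD and range over the
three treatment groups), not the per-group slopes. The waterborne triple
(0.23, 0.38, 1.25 μg g⁻¹ d⁻¹) is forced by its summary: with the printed
mean and range, the middle value is $3 \cdot 0.62 - 0.23 - 1.25 = 0.38$.
The dietary triple is under-determined by the rounded summary
(0.05 ± 0.02, range 0.02–0.07); we fixed (0.02, 0.05, 0.07) because the
implied per-group waterborne shares (92.0 / 88.4 / 94.7%) then sit inside
the published 87.9–95.3% range, whereas the alternative middle value 0.06
would push one group's share below it. This choice was made once, from the
printed constraints, and is not a tuning knob.

## What the generator does and does not emulate

The generator is the exact algebraic inverse of the accounting: measured
waterborne concentration is $(C_{bg,w} + J_w t)\,\varepsilon$ and dietary is
$(C_{bg,d} + J_d t / S)\,\varepsilon'$, so the pipeline's $\times S$ step
recovers the daily-equivalent dietary influx exactly. Consequences for
interpreting green tests:

* A zero-noise simulation **must** be recovered to floating-point accuracy —
  this validates the plumbing, not the biology.
* With noise, parameter-recovery tests validate estimator *bias and
  variance under the stated noise model* — not robustness to model
  violations (elimination, nonlinear uptake, assimilation-efficiency
  variation, tank effects), none of which the generator produces by default.
* Biological between-animal variability and measurement error are not
  separately modelled, because the accounting cannot distinguish them; the
  single `noise_cv` absorbs both.
* No depuration phase, no algal labelling kinetics, no growth dilution
  (sizes are drawn independently of group, matching the no-growth-effect
  finding the design assumes).

## Numerical and procedural choices

* **Negative cells are flagged, not clipped.** When measurement noise
  exceeds a small dietary signal, a cell's mean new accumulation can be
  negative. Clipping to zero would bias apportionment toward the waterborne
  route, so such cells are flagged, warned about, and excluded from
  apportionment summaries (the exclusion count is reported).
* **Apportionment is cell-level.** Shares are computed from cell means
  (group × day), then summarized across the nine treatment cells; this
  matches the mean ± SD over a small number of cells style of reporting.
  Per-animal shares would be noisier and would require pairing individual
  animals across routes, which the cell means already do implicitly.
* **No synthetic (0, 0) point** is added to the regressions; pseudo-data
  distorts standard errors.
* **Spike purity is recorded but not applied** as a concentration
  correction by default; the accounting operates on measured isotope
  concentrations directly. (At purities of 93–99% the correction is within
  measurement noise; a sensitivity analysis can apply it externally.)
* **Influx and share summaries use the sample (n−1) SD** over groups/cells,
  matching mean ± SD reporting conventions for small numbers of units.
* **Bootstrap** resamples animals with replacement *within* each
  group × day stratum, control strata included, so background-estimation
  uncertainty propagates into the CI; percentile intervals (type-7
  quantiles) are reported. Degenerate data (noise-free) legitimately yield
  a zero-width interval.
* **ANOVA is classical one-way** (equal-variance) with Tukey HSD post-hoc
  letters (greedy compact-letter-display insertion; adequate for ≤ ~6
  groups). No Welch correction by default, and no multiple-testing
  correction across days or variables — a documented limitation, matching
  common reporting practice for such designs.
* **A constant paired difference** (e.g. every cell exactly 50/50) makes
  the paired *t* statistic undefined (zero variance); the comparison then
  reports p = 1 for a zero difference and p = 0 otherwise, rather than NaN.

## Why small dietary signals are intrinsically noisy

The $\times S$ scaling multiplies not only the dietary signal but also the
measurement noise of the dietary concentration. At day 10 in the lowest
treatment group of the default scenario, the daily-equivalent dietary
accumulation is $J_d t = 0.2$ μg g⁻¹ while the measured concentration is
dominated by the background (0.895 μg g⁻¹); with a 5% noise CV, the scaled
per-animal noise SD is $S \times 0.05 \times 0.895 \approx 0.36$ μg g⁻¹ —
larger than the signal — giving the cell mean (n = 6) a standard error of
about 0.15. By the delta method the cell's waterborne share then has an SD
of roughly 5 percentage points. Early-time, low-dose cells therefore
scatter widely (occasionally even to negative dietary means, hence the
exclusion flag), and any guarantee about *individual* cell shares across
many simulated replicates is unattainable in this stated world. The
acceptance suite accordingly checks per-cell shares aggregated across
simulations, and influx-rate recovery (which pools all three days) at the
per-replicate level.

## Known limitations

* The linear, no-elimination model is a short-exposure approximation; the
  package deliberately computes no uptake rate constants normalized by
  exposure concentration, no elimination rates and no steady-state
  extrapolations.
* Tank variance is not modelled in the analysis (tanks are replicates);
  the simulator's `tank_cv` exists precisely to study when that assumption
  breaks the nominal error rates.
* Units are fixed (μg L⁻¹ water, μg g⁻¹ dw tissue, days) and never
  auto-converted.
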