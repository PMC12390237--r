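# dualtracer

Analysis of **stable-isotope dual-tracer bioaccumulation experiments** in
aquatic animals, in which two stable isotopes of the same metal label the
two uptake routes simultaneously — one isotope spiked into the water
(waterborne route) and the other bound to the food (dietary route) — so that
a single animal yields an independent measurement of each route's
contribution.

The package was built around a cadmium exposure of the freshwater mussel
*Anodonta woodiana* (waterborne Cd-112 plus dietary Cd-113 carried by the
green alga *Chlorella vulgaris*), but every design parameter — groups,
exposure levels, tanks, sampling days, feeding window, tracer isotopes — is
configurable. It is intended for ecotoxicologists running or re-analysing
route-apportionment exposure experiments, and for methodologists who want a
tested simulator of such experiments.

## The accounting and the statistics

For an animal sampled on day *t* from treatment group *g*:

- **Background.** Unexposed (control) animals carry each tracer isotope at
  its share of the natural metal burden. The background is the control-group
  mean concentration of the tracer, `C_bg` (pooled over sampling days by
  default).
- **Daily-equivalent scaling.** When food is available only `h` hours per
  day, dietary-tracer measurements are multiplied by `S = 24 / h` (here
  `S = 24 / 3 = 8`) to put the dietary route on a per-day basis.
- **New accumulation.** `ΔC_w = C_w − C_bg,w` for the waterborne tracer and
  `ΔC_d = S · (C_d − C_bg,d)` for the dietary tracer (μg g⁻¹ dw).
- **Influx rate.** `J_in` (μg g⁻¹ d⁻¹) is the ordinary-least-squares slope
  of new accumulation on exposure day, per group and tracer:
  `ΔC = a + J_in · t + ε`.
- **Relative importance.** Per group × day cell,
  `f_w = 100 · ΔC̄_w / (ΔC̄_w + ΔC̄_d)` percent waterborne (complement
  dietary), summarized as mean ± SD and range over the treatment cells, with
  a stratified nonparametric bootstrap CI for the mean.
- **Supporting tests.** One-way ANOVA with Tukey HSD compact letter displays
  for growth variables; paired *t*-test of waterborne vs dietary share;
  tracer-specificity and spike-recovery QC arithmetic; total background
  metal inferred from a tracer concentration and its natural isotopic
  abundance.

The synthetic-data generator is the exact inverse of this accounting:
measured concentrations are `(C_bg + J·t) · ε` (dietary: `J·t/S`) with
multiplicative mean-1 lognormal noise, so a noise-free simulation must be
recovered perfectly by the pipeline — and is, to ≤ 1e−9 relative error
(tested).

## Worked example

```r
library(dualtracer)

sc  <- anodonta_scenario(noise_cv = 0.05)          # design + ground truth
tab <- simulate_experiment(sc$config, sc$truth, seed = 7)
rep <- run_analysis(tab, sc$config, bootstrap_reps = 500, seed = 7)
print(rep)
#> <dualtracer_report>
#>   backgrounds: 1.53 (waterborne) / 0.88 (dietary) ug/g dw
#>   J_in waterborne 0.636 +/- 0.568, dietary 0.0512 +/- 0.0328 ug/g/d (fold 12.4)
#>   waterborne share 91.8 +/- 3.5% over 9 cells (ratio 11.3)
```

Reading the output: the recovered backgrounds (1.53 / 0.88 μg g⁻¹ dw) match
the simulated truth (1.52 / 0.87); the mean waterborne influx rate
(0.636 ± 0.568 μg g⁻¹ d⁻¹ across the three treatment groups) is ~12-fold
the dietary rate; and the waterborne route accounts for 91.8 ± 3.5% of new
accumulation across the nine group × day cells (bootstrap 95% CI
89.3–93.9%), i.e. an animal of this kind predominantly reflects *waterborne*
metal when used as a biomonitor. The paired *t*-test of waterborne vs
dietary share across cells gives t(8) = 36.0, p ≈ 4e−10.

Per-group influx estimates with fit diagnostics:

```r
rep$influx$per_group[, c("group", "route", "j_in", "slope_se", "r_squared")]
#>   group      route       j_in    slope_se  r_squared
#> 1    T1    dietary 0.01384798 0.010737430 0.09416727
#> 2    T2    dietary 0.06414476 0.008996868 0.76059476
#> 3    T3    dietary 0.07549636 0.015613936 0.59369280
#> 4    T1 waterborne 0.24931251 0.009339621 0.97803928
#> 5    T2 waterborne 0.37027104 0.012211686 0.98289439
#> 6    T3 waterborne 1.28731451 0.038777446 0.98568968
```

Note the low R² for dietary T1: at a true daily-equivalent influx of only
0.02 μg g⁻¹ d⁻¹ the ×8-amplified measurement noise rivals the signal — the
vignette discusses why this is intrinsic to feeding-window designs.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli/dualtrace.R", package="dualtracer"))') \
  simulate --config inst/extdata/config.yaml --truth inst/extdata/truth.yaml \
  --seed 1 --out measurements.csv
# then: analyze --config ... --measurements measurements.csv --out report.json
```

Subcommands: `simulate`, `account`, `kinetics`, `apportion`, `analyze`.

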