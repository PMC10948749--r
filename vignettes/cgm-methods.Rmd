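---
title: "Models and methods behind cgmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cgmetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmetrics)
```

`cgmetrics` packages three things: a glycemic-variability (GV) index
engine, a generative model of a two-cohort CGM study, and the statistical
stage used to compare cohorts and correlate indices with biomarkers. This
vignette records the models, the defaults, and the choices made where the
design was genuinely open.

## Trace handling

Traces are long data frames (one row per reading) with glucose in mg/dL,
restricted to the sensor reporting range [40, 500]. `resample_to_grid()`
places readings on a regular grid (default 15 minutes, the historic-log
cadence of flash CGM sensors) anchored at local midnight of each subject's
first reading, interpolating linearly between observations. Grid points
farther than `max_gap` (default 60 minutes) from any observation are
emitted as missing: indices like MAGE are sensitive to filtering, so no
smoothing or gap imputation is ever applied. Days with less than 70% of
grid points present are excluded from all summaries; the 70% floor follows
common CGM consensus practice.

`analysis_window()` keeps calendar days 2–14 (day 1 = sensor activation
day), discarding the first day's output, which is known to be noisy while
the sensor settles. Each subject's activation date travels with the trace,
so windowing is idempotent and day numbering survives regridding.

## The index battery

Per day (all on the non-missing grid values): mean; sample SD (n − 1
denominator everywhere — with 96 readings per day the distinction is
cosmetic, but one flavor is fixed for reproducibility); CV = 100·SD/mean;
dwell percentages TIR [70, 180] (closed bounds), TAR > 180, TBR < 70 — the
three partition 100 exactly — and the restricted rTIR [70, 110] used by
wellness-oriented platforms.

**MAGE** uses the classic turning-point formulation: scan sign changes of
the first difference with plateaus merged, treat the day's first and last
readings as boundary extrema, and average the amplitudes between
consecutive extrema that exceed the day's SD, counting both rising and
falling excursions. Published MAGE implementations disagree in their
details; this variant is fixed and cross-checked in the tests against an
independently coded brute-force oracle on hundreds of randomized fixtures.
A monotone or constant day yields 0.

**Risk indices** use the standard mg/dL parameterization of the
symmetrizing transform, f(BG) = 1.509·((ln BG)^1.084 − 5.381), stored in
one place. Risk is 10·f², split into a low component (f < 0) and a high
component (f > 0); LBGI/HBGI are the per-day means, the daily risk range is
the day's max low + max high, and ADRR averages the daily risk range over
valid days. The root of f sits at ≈ 112.5 mg/dL, so a trace pinned there
scores ≈ 0 on all four.

**CONGA(n)** is the sample SD of within-day differences n hours apart
(default n = 1, configurable to 2 or 4 — platform conventions differ and
no single lag is canonical). **MODD** averages |G(d+1, t) − G(d, t)| over
matched clock slots of consecutive valid days, skipping pairs with a
missing member and never pairing across a gap of excluded days.

## The synthetic study

The generator emulates a 14-day, 15-minute study of 53 healthy and 52
pre-diabetic adults. Per subject:

glucose(t) = baseline(day) + circadian(t) + meals(t) + AR(1) noise,
clipped to [40, 500].

* **Baseline**: cohort mean + a latent dysglycemia factor z ~ N(0, 1)
  scaled by a per-cohort loading + a subject intercept + per-day jitter +
  a small negative per-day drift (both printed cohorts improved over the
  wear period).
* **Circadian**: a 24-h cosine peaking late afternoon plus a Gaussian
  nocturnal dip centred 03:30 — nocturnal lows are what give healthy
  cohorts their below-range minutes.
* **Meals**: three pulses per day (08:00/13:00/20:00 ± 30 min jitter) with
  lognormal amplitudes and a gamma-like rise/decay (time-to-peak 40–45
  min). The pre-diabetic preset has a heavier amplitude tail and slower
  decay, which is what produces its above-180 exposure.
* **Noise**: stationary AR(1) at 15-minute steps (ρ = 0.8) — CGM error is
  strongly autocorrelated, and white noise would inflate short-lag
  differences (CONGA) relative to within-day SD.

The same z scales meal amplitudes and loads on the biomarker panel (HbA1c,
OGTT, fasting glucose, log-insulin, log-Hs-CRP), so a subject with high
realized GV also tends to have higher insulin resistance — the mechanism
behind the positive J-index ↔ HOMA-IR correlation in the pre-diabetic
cohort (nominal r ≈ 0.4; setting `latent_loading = 0` severs it). Screen
biomarkers are drawn truncated inside the ADA eligibility bands (healthy:
FBG 79–99 mg/dL, HbA1c 4.0–5.6%, OGTT < 140; pre-diabetic: 100–125,
5.7–6.4, 140–199). HOMA-IR is derived as glucose·insulin/405 from a
simulated lognormal fasting insulin; Hs-CRP presets give the pre-diabetic
cohort roughly twice the healthy level. Activity (steps, heart rate,
sleep) carries weak latent couplings with cohort-specific signs.

Preset calibration: the constants in `inst/extdata/cohort_presets.yaml`
were fit once, by iterating the full pipeline against the reference cohort
summaries (healthy ≈ 102.4 mg/dL mean / 16.2 SD / 95.3% TIR / 30.7 MAGE;
pre-diabetic ≈ 112.2 / 19.4 / 17.3% CV / 1.4% TAR), then frozen. Two
printed quantities cannot be satisfied jointly: the reference TIR/TAR/TBR
means do not sum to 100 for the healthy cohort, while the computed ones
partition exactly; calibration favours TIR and TAR, letting TBR absorb the
remainder (≈ 4% rather than the printed 1.6%). Likewise the amplitude tail
needed for the pre-diabetic TAR pushes its MAGE (~36 mg/dL) above the
printed 32.9. What passing calibration shows is that the *pipeline*
recovers the statistics of data generated under this model — not that the
model captures real meal logs, exercise, compression lows at night, or
sensor dropout bursts, none of which are simulated.

## The metabolic-score surrogate

Daily composite scores offered by CGM apps are proprietary; `cgmetrics`
defines an explicit, documented surrogate built from exactly the three
ingredient families such scores draw on: `metscore = 0.40·gv + 0.35·tir +
0.25·mean`, where `gv = 100·(1 − min(CV/36, 1))` (36% is the consensus
variability threshold), `tir` is the rTIR dwell percentage itself, and
`mean` is a trapezoid that is 100 on [70, 110] mg/dL and falls linearly to
0 at 40 and 250. Weights and anchors are configuration, not code, so the
score can be re-fit; whether real scores use within-day or rolling-window
GV is undisclosed, and the surrogate's choices are its own. It makes no
claim of numerical agreement with any app-displayed value — only the
qualitative behaviour is asserted: monotone in each ingredient, healthy >
pre-diabetic daily means on simulated cohorts, negative correlation with
HOMA-IR and OGTT.

## Statistics stage

* **Outliers**: one pass, ±3 SD for normal-looking variables, Q1 − 3·IQR /
  Q3 + 3·IQR otherwise, with type-7 (linear interpolation) quantiles —
  stated because the 3×IQR fences depend on the quantile definition.
* **Correlation**: Shapiro–Wilk at α = 0.05 on each variable gates
  Pearson (both pass) vs Spearman. No multiplicity correction by default,
  matching per-cell presentation of correlation tables; `adjust = "BH"`
  enables Benjamini–Hochberg.
* **Cohort × day comparison**: `lm(value ~ cohort * day)` with day
  categorical (per-day means are plotted in such studies; no trend shape is
  assumed), type-II tests, complete-case per endpoint-day cell, and per-day
  least-squares means with 95% CIs via `emmeans`. Repeated measures per
  subject are deliberately not modelled — the module documents a
  complete-case two-factor analysis rather than guessing at a mixed model.
* **ANCOVA**: `end ~ cohort + baseline`; a constant baseline degrades to
  the unadjusted comparison with a warning.
* **ROC**: empirical trapezoidal AUC (`pROC`), oriented so that the cohort
  with the higher index mean is the predicted class; the tests verify the
  AUC = U/(n₁·n₂) Mann–Whitney identity exactly.

## Problem sizes used in the test suite

Monte-Carlo checks run at sizes chosen to keep the default suite fast
while leaving conservative statistical margins: oracle equivalence for
MAGE/CONGA/MODD/ADRR on 200 randomized fixtures; ANOVA type-I error on 200
null replicates (2 × 25 subjects × 4 days); calibration recovery on two
replicate cohorts per arm; correlation-sign recovery on 12 replicate
pre-diabetic cohorts (and 4 zero-loading cohorts, testing that the
*expected* cross-correlation is near zero); drift-sign on 5 replicates of
20 subjects. All seeds are fixed; the acceptance script derives its 10
simulation seeds from the single `--seed` argument.

## Known limitations

Meal timing is clocked, not logged; no exercise, stress or medication
effects; sensor error is Gaussian-AR(1) with no dropout bursts or
compression artefacts; biomarkers are cross-sectional draws, not
longitudinal; the two-way ANOVA treats subject-days as independent, as
documented above. The index engine itself is general and applies
unchanged to real exported CGM CSVs via `run_pipeline(input_dir = ...)`.
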