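---
title: "Event-anchored time-series features for cardiac-arrest prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-anchored time-series features for cardiac-arrest prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrestcast)
```

## The problem

Children in intensive care arrest far more often than ward patients, and a
large share of those arrests are the endpoint of *progressive shock*: an
insidious deterioration of vital signs over minutes to hours, with the
steepest changes concentrated in the final 10–15 minutes. Conventional
bedside scoring tools use one value per variable (a *multivariable* data
paradigm) and therefore cannot see deterioration at all. This package
implements a complete workflow for building classifiers that combine the
conventional single-value features with explicit time-series information:
event-anchored windowing, imputation, clinically derived latent variables,
trend features, feature-subset construction, feature reduction, model
training with cross-validation, and holdout validation.

Because no patient-level ICU dataset ships with the package, a synthetic
cohort simulator is a first-class module: it generates labelled
arrest/control episodes whose statistical structure matches the physiologic
premise above, so every downstream stage is exercised end to end with no
external data.

## The synthetic cohort model

Each case emits per-minute heart rate (HR), oxygen saturation (SpO2,
a fraction), and arterial systolic/diastolic pressure (SBP/DBP), plus a
sparse noninvasive blood-pressure pair, one hemoglobin lab and demographics.
The generative model per channel is

  value(t) = baseline + drift(t) + e(t),   e(t) = ar1 · e(t−1) + innovation,

a stationary AR(1) noise process (default lag-1 autocorrelation 0.8) around
a pediatric baseline (HR 120 bpm, SBP 95 mmHg, DBP 55 mmHg, SpO2 0.97).
For arrest cases, drift is piecewise linear: from a per-case random shock
onset (Uniform(2, 8) hours before the event) a slow drift applies
(default −3 mmHg/h SBP, −2 mmHg/h DBP, +4 bpm/h HR, −0.002/h SpO2), and in
the final 15 minutes a terminal drift is added (−1.5 mmHg/min SBP,
−1 mmHg/min DBP, +1.5 bpm/min HR, −0.004/min SpO2). The piecewise-linear
form is the simplest one exhibiting both the "minutes-to-hours" insidious
decline and the documented terminal acceleration; the magnitudes are
documented assumptions chosen to produce a clinically plausible
compensated-to-uncompensated transition, not literature estimates, and all
are configurable.

Controls receive a uniformly random interior reference time with at least
13 h of prior monitoring, so both classes are windowed identically and
record length cannot act as a confound. Cohorts are balanced 1:1 by default
because balanced designs are what the modeling stage expects; the ratio is
configurable. Values are clipped to physiologic hard bounds (positive rates
and pressures, SpO2 ≤ 1) with clip counts logged on the case record.
Noninvasive pressures are the arterial series sampled at a per-case fixed
interval drawn from {5, 15, 30, 60} minutes plus independent cuff noise
(SD 4 mmHg); clinically neither modality is uniformly more accurate, so
both are kept as candidate features. Per-case sub-seeds are derived by a
stable integer hash of (master seed, case index), which makes whole-cohort
simulation reproducible to the byte.

What the simulator does *not* emulate: non-shock arrest mechanisms
(arrhythmia, embolism, unplanned extubation), temperature and activity
channels, operator-controlled lab-draw frequency, and any cross-channel
physiologic coupling beyond the shared drift schedule. Passing tests
therefore demonstrate that the machinery extracts trajectory information
when it is present and finds none when it is absent — they are not evidence
about real PICU data.

## Event-anchored representation

All streams are re-expressed relative to the reference event (arrest time,
or the control anchor); observations after the reference are dropped
outright, which is what makes the no-future-leakage property testable as a
hard invariant rather than a convention.

Two resolutions are used. The final hour is a per-minute grid of 60 slots,
t = −59 … 0. Slot t = 0 holds the *multivariable representative* — the
latest measurement before the event — and is excluded from the time-series
block, which therefore contributes 59 minute-level elements per channel.
This convention reconciles the two accounting facts the representation must
satisfy: 59 per-minute time-series elements alongside hourly averages of 60
native measurements. The 12-hour lookback contributes 12 hourly means; bin
h covers t ∈ [−60h, −60(h−1)−1], so the most recent bin overlaps the
minute-resolution hour. Whether the hourly window should instead exclude
that hour is genuinely ambiguous; we include it (uniform 60-minute
averaging over the full lookback) and treat the overlap as harmless
redundancy that the feature-reduction stage can discard.

Missing slots are filled by carry-forward with unlimited lookback within
the record, falling back to a configurable per-channel normal value
(HR 100, SBP 100, DBP 60, SpO2 0.98, Hgb 12 — implementation defaults)
when no prior observation exists. Carry-forward is deliberately
conservative and real-time-safe: it never looks forward. Every slot keeps a
provenance flag (`observed`/`carried`/`normal`) so stale values remain
auditable. Timestamps are integer minutes; sub-minute data must be
pre-binned (last value wins) before entering the pipeline.

## Latent variables

Four bedside shock calculations are derived pointwise on the grids and as
multivariable representatives:

* pulse pressure `PP = SBP − DBP` (mmHg),
* mean arterial pressure `MAP = (SBP + 2·DBP)/3` (mmHg) — the standard
  formula; no specific form is canonical in this setting, so the textbook
  one is used,
* shock index `SI = HR / SBP` (bpm/mmHg), capped at 10 with a per-point
  flag if SBP ≤ 0,
* oxygen-delivery index `ODI = HR × PP × SpO2 × Hgb`, a semiquantitative
  supply-side surrogate. SpO2 is a fraction everywhere inside the package;
  percent-scale saturations are rejected at the boundary.

Hemoglobin is sparse, so its latest pre-window value is broadcast across
the grid rather than trended — consistent with treating labs as
multivariable features. A central-venous-pressure gradient (MAP − CVP)
would be the more faithful perfusion quantity but CVP is rarely available,
so MAP alone is the latent. MAP is included as a modeled feature but
carries its own channel name (`map`) so it can be ablated via the
configuration.

## Trend features

For each window W ∈ {5, 10, 15, 60} minutes the package computes the OLS
slope (units/min), the intercept anchored at t = 0 (the projected value at
the event, so intercepts are comparable across windows), the window mean,
and slope/mean (1/min) — the last targeting the "steeply falling *and*
already low" configuration that best signals decompensation. Six
between-window mean ratios (5/10, 5/15, 5/60, 10/15, 10/60, 15/60) complete
a 22-feature block per channel. Windows include the t = 0 slot: a W-minute
window is the W most recent grid points, maximizing use of the freshest
data. Denominators smaller than 1e−9 in magnitude yield feature value 0
with a cleared validity flag; degenerate cases stay in the matrix rather
than breaking rectangularity. Trend blocks are computed for the six raw
continuous channels and the four latents (220 features), restrictable via
configuration.

## Subsets, partition, reduction, models

Features are tagged MV / TS / CLIN / TREND, and five modeling subsets are
instantiated: MV (baseline), MV+TS, MV+TS+CLIN, MV+TREND, and ALL. With the
default roster (6 continuous channels, 4 latents, 3 demographics/labs) the
widths are 13 / 439 / 723 / 233 / 943; the builder asserts this ledger at
run time.

A stratified 33% holdout is withheld before any selection or training; the
per-class allocation uses largest-remainder rounding, and the holdout
object carries a distinct class that the selection and training functions
refuse, enforcing by construction that holdout rows are scored exactly
once. Stratification (rather than a simple random split) stabilizes
holdout accuracy at cohort sizes of ~100, where one case moves the estimate
by ~3%.

Two reduction strategies are provided. RFE here is model-independent
backward elimination: the ranking criterion is the standardized two-group
mean difference (z-scored on the train partition only), dropping the
lowest-scoring 20% per round (one-at-a-time available via `drop_frac = 0`)
until the target count — default 30 — remains; ties break by column order
so the trail is deterministic. SVMW trains one linear-kernel SVM (cost 1)
on all standardized features and adds features by descending absolute
weight from a single fit; repeated refitting during forward addition is a
plausible variant but a single ranking fit is the default for
determinism and speed. The criterion is pluggable, so classic SVM-driven
RFE can be recovered by combining the two pieces.

Four families train on standardized features with stratified N-fold
cross-validation (default 10) as the internal-validity measure: logistic
regression (with an OLS-on-0/1 fallback flag, since "linear regression" on
a binary target is best read as the regression-family baseline), a
decision tree (unlimited depth, minimum leaf 5, no complexity pruning), a
single-hidden-layer neural network (16 units, weight decay 0.01, seeded
initialization), and a linear SVM (cost 1). These defaults are deliberate
implementation choices — no tuning is performed, because the object of
study is the feature sets, not the algorithms. The score threshold for
sensitivity/specificity is 0.5; no operating point is optimized. AUROC is
computed by the midrank statistic (ties count one half), which the tests
pin against exhaustive pairwise enumeration.

`compare_subsets()` runs the full factorial (5 subsets × {RFE, SVMW, NONE}
× 4 families) on one fixed split; the NONE cells train without reduction
and report the train-vs-holdout accuracy gap as the overfitting estimate.
Predictive values are reported but flagged non-interpretable under a
balanced design, because they do not reflect true arrest prevalence.

## Numerical and degenerate-input choices

* Constant features z-score to all zeros (SD substituted by 1) rather than
  NaN; their univariate score is 0, or infinite if the class means differ
  with zero pooled SD (perfect separation is flagged, not hidden).
* An empty channel yields a full normal-value grid and a flagged MV
  representative; a completely empty case still emits a complete row.
* A reference time before the first observation returns an empty aligned
  series with a warning; downstream imputation handles it.
* All randomness flows from explicit integer seeds (simulation, splits,
  folds, network initialization); derived seeds stay below 2^31.

## Problem sizes in the shipped checks

The package's own test suite and the reproduction script size their
simulations to keep a full run in the low minutes on one CPU while leaving
the Monte-Carlo margins wide: null-calibration uses 100 cohorts of 200
cases (multivariable block), the matched-baseline trend experiment 100
cohorts of 50 cases at a reduced factorial (MV vs MV+TREND, RFE,
linear + SVM), and selection-recovery 100 replicates of a 100 × 50 matrix
with three 2-SD informative features. The reproduction script
(`scripts/acceptance.R`) repeats the same experiments at 30 replicates
where the test suite uses 100.

## Known limitations

* The simulator's independence across channels (given the drift schedule)
  understates the cross-correlation of real vital signs; absolute holdout
  performance on synthetic cohorts is therefore optimistic and should be
  read as a mechanism check, not a clinical estimate.
* Seasonality/recurrence features are deliberately out of scope (the
  target is a first event).
* The MV variable roster is a documented reconstruction
  (HR, SpO2, arterial and noninvasive pressures, Hgb, age, weight) and is
  configuration-driven rather than fixed.
* The hourly-window overlap question above is resolved by a default, not
  by evidence; both behaviors are reachable through `window_spec()`.
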