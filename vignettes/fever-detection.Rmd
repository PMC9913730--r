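---
title: "Detecting fever in calves from tail-base surface temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fever in calves from tail-base surface temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calffever)
```

## The problem

Bovine respiratory disease (BRD) is the main health and economic burden in
backgrounding operations, where beef calves arrive at 3–4 months of age and
are commingled in group pens. Fever precedes most clinical signs, but rectal
thermometry does not scale to hundreds of animals twice a day. A wearable
sensor at the ventral tail base records skin ("surface") temperature (ST)
every 10 minutes and offers a scalable proxy — if its signal can be turned
into a reliable fever indicator.

Two obstacles stand between raw ST and a usable fever alarm:

* **The diurnal rhythm.** ST follows a strong daily cycle (lowest around
  06:00, highest around 17:00, aligned with feeding), with an amplitude that
  differs between calves and from day to day. An absolute threshold on raw
  ST is useless.
* **Sensor artifacts.** Dropped records, out-of-range spikes when the sensor
  detaches, and step jumps when it shifts against the skin.

`calffever` implements the full analysis chain that addresses both, plus a
synthetic-trace generator so that every stage is testable without farm data.

## From raw records to the fever indicator

**Preprocessing** (`preprocess_st()`) applies three rules in a fixed order:

1. *Extreme-value filter*: records with temperature ≤ 30 °C or ≥ 45 °C are
   removed (bounds inclusive).
2. *Jump filter*: scanning in time order, any record differing by ≥ 1.0 °C
   from the last **retained** record is removed. Comparing against the last
   retained record (rather than the immediate predecessor) means a single
   spike cannot delete its valid neighbours, while a step artifact is
   treated as invalid until the signal returns near the retained level.
   Which record of an offending pair to drop is a genuine choice; dropping
   the later one keeps the scan causal and idempotent.
3. *Hourly maximum*: the per-hour maximum damps transient dips; hours with
   no surviving records stay absent (gaps are represented by absence, never
   by sentinel values).

**Four measurements** are computed on the hourly grid
(`st_transforms()`):

* raw hourly ST;
* **estimated ST**:
  `Est = Tem + (Max24 − Tem) × (Max24 − Min24 − 0.9) / (Max24 − Min24)`,
  where `Max24`/`Min24` are the extremes of the trailing 24 h (current hour
  inclusive). The 0.9 °C constant is a reference daily range established in
  prior experimental-infection work; the formula rescales each calf-day's
  observed range onto that reference band, standardizing between-calf and
  between-day differences in rhythm magnitude. When the observed range is
  degenerate (`Max24 == Min24`) there is no rhythm to correct and the value
  passes through unchanged — also the formula's natural limit;
* **rST** (residual ST): the value minus the mean value at the same clock
  hour over the previous 3 days — this removes the rhythm and the calf's
  individual baseline;
* **estimated rST**: the residual of the estimated ST (estimate first, then
  residualize). This is the fever indicator used downstream.

Numerical choices for the transforms: the 24-h window requires at least half
of its 24 hourly slots (≥ 12) or the estimate is undefined; the residual
requires at least 2 of the 3 same-time baseline values (robust to dropouts
without discarding most of the series). Undefined values propagate as
absence. The trailing window and baseline are computed on the hourly grid,
consistent with the hourly-maximum extraction.

**Fever labeling** (`label_fever()`): fever is an estimated rST of
≥ 1.0 °C sustained over 4 consecutive hours; a data gap breaks a run. All
hours of a qualifying run are labeled 1, including the first three — the
classification task is per-hour recognition of fever periods. (A
`confirmed_only` switch restricts labels to hours from the fourth onward,
for users who want alarm-time semantics.)

**Features** (`extract_features()`): for each hour, the minimum and maximum
of the estimated rST over trailing windows of 3, 6, 12, 24 and 48 h, plus
the signed differences between the current value and each extremum — 20
features. Windows are trailing and inclusive of the current hour, so the
min-differences are ≥ 0 and max-differences ≤ 0 by construction; the
alternative reading of the "difference" features (current extremum minus an
earlier window's extremum) is rejected because the abstract formulation
("difference between the current value and 24- and 48-h minimum")
determines the sign structure. Rows need every window at least half
populated. Optional per-calf arrival metadata (sex, season at introduction,
arrival age, weight, chest circumference, blood line) join by calf, with
categories one-hot encoded (no reference level dropped — trees need none).

**Classifier** (`fever_rf()`): a 100-tree random forest on an 80/20
record-level random split, with repeated 10-fold cross-validation on the
training set as an overfitting diagnostic (3 repeats by default; the final
model is refit on the full training set), classification at a fever
probability > 0.5, and variable importance as mean decrease in Gini
impurity. Beyond the tree count, hyperparameters stay at conventional
defaults (√p candidate features per split, unlimited depth). A record-level
split mirrors the protocol's wording; because consecutive hours of one calf
are correlated, a grouped `split_unit = "calf"` alternative is provided for
leakage-free evaluation.

**Rectal association** (`run_rectal_experiment()`): twice-daily rectal
temperatures (08:00–09:00 and 16:00–17:00) are paired with the temporally
closest defined hourly value of each measurement — preferring the hour that
contains the rectal timestamp, falling back to the nearest defined hour
with ties broken toward the earlier one, and discarding pairs more than
60 min apart. Each measurement is then regressed against rectal temperature
by OLS and compared by R². Two deliberate choices: the repeated-measures
structure of the original analysis is approximated by optional calf fixed
effects (`adjust_calf`), with the default R² taken from the simple
regression; and the comparison is restricted to rectal observations paired
under **all four** measurements, because the residual measurements are
undefined during the first days and comparing R² across different
subsamples would not be a fair contest.

## What the synthetic generator emulates

No public dataset of this kind exists, so `simulate_calves()` generates
traces with the statistical structure the analysis assumes. Per calf:

```
ST(t) = baseline_i + drift_i(t) + amp_{i,d} · shape(clock(t)) + level_{i,d}
        + fever_i(t) + noise(t)
```

* `baseline_i ~ N(37.8, 0.7)` °C — between-calf offsets dominated by
  attachment pressure, coat and site, not by core temperature;
* `shape()` — an asymmetric cosine interpolation between the 06:00 trough
  and 17:00 peak (11 h ascent, 13 h descent), matching the feeding-driven
  asymmetry of the observed cycle, rather than a pure sinusoid;
* `amp_{i,d}` — a per-calf log-normal factor (σ = 0.3) on the 1.0 °C
  default amplitude, multiplied by a per-day factor (σ = 0.15): rhythm
  magnitude differs between calves and varies day to day. This
  heterogeneity is precisely what the estimated-ST range normalization is
  designed to standardize;
* `level_{i,d} ~ N(0, 0.1)` °C — day-level shifts (weather, behaviour);
* `drift_i(t)` — a slow AR(1) process (stationary sd 0.7 °C, correlation
  time 7 days, interpolated within days): warm/cold spells and gradual
  attachment changes. It moves skin temperature without moving core
  temperature, and the 3-day same-time baseline removes most of it while
  raw ST keeps all of it;
* `fever_i(t)` — episodes arriving at 1.5 per calf-month, with plateau
  elevations of 1.5–3.0 °C, durations of 6–48 h and 3-h linear ramps. At
  these defaults roughly 6–7 % of calf-hours end up labeled febrile —
  the prevalence regime in which accuracy is high and precision the
  binding metric;
* artifacts: 1 % dropouts, 0.2 % out-of-range spikes, 0.2 % step jumps —
  exercising each preprocessing rule.

Rectal temperature follows the *core* trajectory: the population surface
baseline plus a +0.8 °C core-surface offset, the full fever elevation, an
attenuated rhythm (factor 0.15 — core circadian variation is a small
fraction of the feeding/environment-driven skin cycle) and 0.15 °C
thermometer noise. The per-calf surface baseline, amplitude factor, day
effects and drift are deliberately absent from the core trajectory: they
are sensor- and skin-level phenomena. That design reproduces the documented
regime in which raw ST is a weak rectal proxy (R² in the 0.1–0.3 range on
the 34-calf, 7-day comparison design) while the rhythm-removing residuals
track rectal temperature substantially better.

When the metadata effect is enabled, the episode rate is multiplied by
`exp(0.4 · (110 − weight)/15)` and a season factor (winter 1.3, autumn 1.1,
spring 0.9, summer 0.8): lighter calves and cold-season introductions run
higher risk, making the metadata features genuinely informative.

**What the generator does not emulate.** Ambient temperature as a measured
covariate, multi-season effects, sensor-detachment physics, and — most
importantly — the physiological, nonlinear coupling between skin and core
temperature. Within this additive generator the plain rST often edges out
the estimated rST in the rectal comparison, because the estimated
transform's trailing 24-h maximum leaks fever elevations into the following
day; the preference for the estimated variant observed on real farm data
rests on physiology the simulation does not claim to capture. The checkable
claim here is the robust qualitative one: the rhythm-corrected residual
beats raw ST.

Two further consequences for interpreting results on synthetic data: the
fever *labels* are by definition a function of the same estimated-rST
series the features summarize, so near-ceiling classification metrics
demonstrate that the pipeline is internally consistent and the rule
learnable — not that a forest would reach those numbers against clinical
ground truth; and the short-window features (`h3min`, `h3max`) dominating
the Gini importances is the structural echo of the 4-h run rule.

## Reproducibility and problem sizes

Every stochastic step descends from one integer seed: the pipeline derives
per-stage seeds by fixed offsets, so identical configuration and seed give
byte-identical outputs (this is asserted by the test suite, twice). The
forest runs single-threaded with a fixed seed for the same reason.

The test suite exercises the full chain at the study scale — 120 calves ×
30 days (~520 k records, ~76 k feature rows) for the classification
experiment, across three seeds for the importance ranking, and 34 calves ×
7 days for the rectal comparison — alongside exact brute-force oracle
checks of the rolling features and run labeling on 200 random gappy series
and hand-evaluated cases of the estimated-ST formula on both sign branches.
Miniature configurations (≤ 6 calves, ≤ 10 days) cover I/O round-trips,
degenerate inputs (single-class training data, all-negative folds,
zero-variance measurements, empty files) and error surfaces.

## Known limitations

* The jump filter's sequential comparator can discard a calf's entire trace
  if the very first record is itself an artifact; with realistic artifact
  rates this affects a fraction of a calf per 120-calf run, and the
  downstream stages tolerate the resulting short series.
* The 80/20 record-level split leaks within-calf autocorrelation between
  training and test data; it is retained as the default because it mirrors
  the protocol being implemented, and the calf-level split is one argument
  away.
* Undefined metrics (0/0 precision in a fever-free test set) are reported
  as `NA` with a warning, never as 0 or 1.
* The first three days of every calf, and hours failing window coverage,
  carry no label and no features by construction; a deployment would warm
  up sensors before relying on alarms.
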