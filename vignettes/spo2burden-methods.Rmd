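---
title: "Overnight SpO2 burden metrics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overnight SpO2 burden metrics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements: the
signal model, every tunable that matters, the numerical choices made where a
verbal rule had to become code, and what the synthetic-data experiments do
and do not demonstrate.

## The signal and its preprocessing

Home sleep apnea test oximeters record SpO2 at a few hertz with 1%
resolution; the working assumption throughout is a quantized, piecewise-
constant trace at `fs = 3` Hz with a stable overnight baseline near 96-97%,
transient desaturations caused by airway events, and occasional dropouts the
device reports as 0.

Preprocessing is a fixed order: invalid-sample marking, edge trimming,
median filtering, eligibility. The tunables:

* `trim_min` (minutes, default 15): device setup/removal contaminates the
  recording edges; both edges are cut before anything else is measured.
* invalid samples: a reading of 0 is the device's invalid code. By default
  readings outside 50-100% are flagged too - saturations below 50% are not
  survivable readings in this setting and values above 100% are impossible -
  but `strict_invalid_zero_only = TRUE` restores the narrow rule. Values are
  never altered, only masked.
* `median_window_s` (seconds, default 10): the running median removes
  single-sample motion spikes without rounding off genuine desaturation
  edges. The window is centered (30 samples at 3 Hz); with an even length
  the extra sample is taken from the past side. Windows truncate at the
  record edges rather than padding. Invalid samples are excluded from every
  window and pass through unchanged; a window with no valid neighbours
  leaves its sample untouched. Note that a median filter is not exactly
  idempotent on quantized data - a second pass can still move a value by 1%
  where a window straddles a step edge - so the pipeline applies it exactly
  once; the validity mask and the eligibility verdict, by contrast, are
  stable under re-application.
* eligibility: a night must retain at least one hour of signal
  (`min_duration_s = 3600`) and at most 50% invalid samples
  (`max_invalid_frac = 0.5`). Both are assessed on the trimmed record - the
  signal actually analyzed - which resolves an ordering question the verbal
  rules leave open. Ineligible records are reported with the rule that fired,
  never silently dropped.

## Desaturation episodes

Detection works on first differences of the filtered trace. Because the
signal is quantized, "SpO2 is declining" means a maximal non-increasing run:
plateaus (zero difference) extend the current phase, and a run qualifies as
a drop phase when it loses at least `min_drop = 3`% from its starting level
to its minimum. Depth is measured on the filtered signal, onset to nadir.
Several verbal rules required concrete decisions:

* **Onset.** The episode onset is the last sample at the run's starting
  level before the first strict decrease, so a long plateau preceding the
  fall is not counted as part of the event.
* **Recovery.** The recovery phase ends at the first sample back at the
  onset level, searched up to `recovery_window_s = 120` s past the nadir.
  If the signal never returns, the episode ends at the maximum SpO2 within
  that window; ties are broken by the earliest sample. If the window is
  empty (nadir at the end of usable signal) the episode ends at its nadir.
* **Consecutive events.** In periodic breathing a new decline often starts
  before the previous recovery completes. If a new qualifying decline
  begins first, the running episode is closed at the local maximum
  preceding it (which is exactly the next episode's onset sample), so
  episodes are ordered, never overlap in their interiors, and cannot grow
  without bound.
* **Invalid gaps.** An episode may span an invalid gap of up to
  `gap_tolerance_s = 10` s (the gap contributes nothing to its burden); a
  longer gap terminates the episode at the last valid sample. The record is
  effectively segmented at long gaps and each segment is scanned
  independently.
* **Baseline.** Each episode's baseline is the maximum valid SpO2 in the
  100 s before recovery onset (`baseline_window_s = 100`), truncated at the
  record start; the window may include the episode's own drop phase, and if
  it holds no valid sample the onset level is used. The baseline is
  therefore never below the nadir.
* **Burden.** The burden integrates max(0, baseline - SpO2) by the
  rectangle rule at the native sampling interval, in %·s; the normalized
  burden divides by the episode duration (onset to recovery end), giving a
  mean depth in %. A symmetric 6%-deep, 60-s triangular dip yields the
  analytic area 180 %·s and normalized burden 3.0% up to discretization.

The detector is verified against an independent brute-force scanner - an
explicit sample-by-sample walk applying the same rules - episode for
episode, on a thousand random quantized nights mixing event rates 0-60/h
and noise 0-0.6%.

## The seven overnight measures

* `spo2_ent`: Shannon entropy of the empirical distribution of valid SpO2
  values over the signal's native 1% alphabet. Natural log (nats) by
  default, configurable to bits; values are rounded to integer percent
  before tabulation because an even median window can introduce
  half-percent values. The estimator is the plug-in histogram entropy; with
  a constant signal it is exactly 0 and with k equiprobable levels exactly
  ln k.
* `spo2_std`: population (not sample) standard deviation - the features are
  descriptive statistics of the night itself, not estimates for a
  population of nights. This choice is consistent across all SD-like
  quantities and is configurable only by the reader's own code.
* `bab` (below-average burden): area under the night's own mean divided by
  analyzed time. Adding a constant to the signal leaves it unchanged.
* `odb_avg`, `odb_std`, `odb_ent`: mean, population SD, and histogram
  entropy of the normalized episode burdens. The entropy bins are fixed
  width `odb_ent_bin = 0.1` normalized-burden units starting at 0 - the
  burdens are continuous, so an entropy requires a discretization, and a
  fixed absolute width keeps nights comparable; the width is configurable.
  A night with no episodes reports (0, 0, 0).
* `ndb` (nocturnal desaturation burden): cumulative burden over analyzed
  time.

"Analyzed time" is valid recording time after trimming, used consistently
in the `bab` and `ndb` denominators: a reduced-montage oximetry study cannot
measure sleep, so recording time stands in for sleep time.

The postoperative outcome label is computed from the postoperative night:
maximal runs of valid samples strictly below 85% lasting strictly more than
180 s. Invalid samples break a run - two 100-s excursions separated by a
dropout do not qualify. Both comparisons are strict by the rule's wording.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which every package-level claim is demonstrated.

A night is baseline + slow drift (two random-phase sinusoids with periods
of 2 h and 45 min, total SD `baseline_drift_sd = 0.3`%), a Poisson event
process at `event_rate_per_h`, Gaussian noise (`noise_sd = 0.4`%), integer
quantization, and contiguous 30-s invalid blocks totalling
`invalid_frac = 2`% of samples. Events have depth ~ Normal(5, 1.5)%
truncated at 3% and duration ~ Normal(45, 15) s truncated at 15 s, with a
piecewise shape: a linear drop over 30% of the event capped at 12 s (airway
events desaturate quickly; the cap also bounds the lag between the physical
onset and the first quantization step, keeping detected onsets within ~4 s
of truth), a nadir plateau of at least 6 s (so the full depth survives the
10-s median filter), and an exponential-like recovery that returns exactly
to baseline. Events are placed by rejection sampling with a 15-s guard gap;
events that cannot be placed are dropped, and the ground-truth table lists
exactly the events present in the signal. All randomness flows from one
seed through per-subject derived streams, so generation is reproducible and
order-independent.

A cohort draws per-subject covariates (50% women, BMI ~ Normal(30.3, 6.9),
59% cardiorespiratory comorbidity) and a per-subject event rate from a
gamma distribution with mean 20 and SD 19 events/h, matching the published
summary statistics of the surgical population this method targets. The
event rate is the severity ground truth and doubles as a pseudo
apnea-hypopnea index. The respiratory-depression outcome is drawn from a
logistic model on standardized severity, sex, standardized BMI, and
comorbidity (defaults 1.2, 0.5, 0.4, 0.4 on the z/indicator scale); the
intercept is calibrated by Monte Carlo so the expected prevalence is 0.17,
the prevalence reported for this clinical population.

What the generator does **not** emulate: motion artifact with plausible
autocorrelation, oximeter averaging-time distortion, periodic-breathing
event clustering, baseline differences between body positions, or any
physiological coupling between event depth and duration. Tests passing on
this generator therefore demonstrate algorithmic correctness and
statistical behavior of the harness - not clinical performance on real
recordings.

## Prediction and correlation harness

Each overnight measure is evaluated separately: logistic regression of the
outcome on the standardized measure plus sex, BMI (standardized), and the
comorbidity flag, with an L2 penalty (ridge). The penalty strength defaults
to `1/n_train`, the unit inverse-regularization convention; the verbal
specification names the penalty type but not its strength, so the strength
is exposed as `lambda`. The fit uses coordinate descent (glmnet); the
penalized objective, not the optimizer, defines the estimator. Class
weights are inversely proportional to training-fold class frequency.
Continuous predictors are standardized with training-fold statistics only,
to avoid leakage. Age is deliberately excluded.

Splits are stratified 80/20: test counts are fixed per outcome class
(largest-remainder allocation across sex cells), and within each
class-by-sex cell rows are sorted by BMI and sampled one-per-block, which
matches the test fold's BMI spread to the cohort without assuming a
parametric form (a tertile-like systematic scheme). Performance is the mean
over 100 splits of test-set AUC-ROC, and of sensitivity and specificity at
a 0.5 probability threshold; the 95% confidence interval is the 2.5/97.5
percentile of the run distribution (a normal approximation would be the
other defensible choice; percentiles make no symmetry assumption). Sex
strata re-run the harness within one sex with the sex covariate dropped.

Correlations are product-moment with Fisher-transform 95% intervals
(z ± 1.96/sqrt(n-3)); at |r| = 1 the interval is clamped to contain r.
Strength categories on |r|: strong >= 0.8, moderate >= 0.6, fair >= 0.3,
else weak. Sex differences are called non-significant when the two
intervals overlap - a deliberately conservative rule.

Degenerate inputs error loudly rather than guessing: fewer than 4 pairs or
zero variance for a correlation, fewer than 2 valid samples for an SD, a
single-class training or test fold, an outcome class with fewer than two
members at splitting.

## Problem sizes and reproducibility

The shipped tests exercise the pipeline at sizes chosen to make each claim
statistically meaningful while keeping a full run in the low minutes on one
core: 1000 ten-minute nights for the detector-vs-scanner equivalence; 8-h
nights for exact event recovery (0, 5, 20, 50 injected events); 50
two-hour nights per rate level for the monotonicity of NDB, ODB AVG, BAB,
and SpO2 STD across rates 5-60/h; a 200-subject noise-free cohort for the
NDB-severity correlation (r > 0.8); and a 300-subject cohort with a strong
severity effect (coefficient 2.0) for the prediction harness, where the
burden measures reach mean AUC above 0.75, the fitted severity coefficient
is positive in essentially every run, per-run label permutations average to
chance AUC, and a separable toy feature scores exactly 1. The full pipeline
is byte-for-byte reproducible under a fixed seed. `scripts/acceptance.R`
recomputes all of these quantities from scratch.

## Known limitations

* The entropy estimators (signal alphabet, burden bin width) are exposed as
  configuration because no canonical estimator exists for these quantities;
  absolute entropy values are therefore comparable only within a fixed
  configuration.
* The detector assumes the 1%-quantized, few-hertz signal class it was
  designed for; on high-resolution or heavily smoothed traces the
  non-increasing-run logic would fragment or merge events and the filter
  window would need retuning.
* Single-feature models only: the harness deliberately fits one measure at
  a time (plus demographics) to keep measures comparable; no feature
  combination or selection is provided.
* Synthetic validation bounds what can be claimed: the generator's
  assumptions are the test's assumptions.
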