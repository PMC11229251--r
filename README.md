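# spo2burden

Overnight pulse-oximetry (SpO₂) is the cheapest continuously recordable
signal that reflects the repetitive airway obstruction of sleep apnea.
`spo2burden` characterizes sleep-apnea severity from a single preoperative
overnight SpO₂ trace — no airflow, EEG, or manual scoring — and evaluates how
well the resulting measures predict **postoperative respiratory depression**,
operationalized as at least one postoperative hypoxemia episode with
SpO₂ < 85% lasting more than 3 minutes. It is aimed at sleep/anesthesia
researchers and at anyone building oximetry-only screening tools.

## What it computes

From a preprocessed trace (first/last 15 min trimmed, invalid samples
flagged, 10-s median filter), the package detects **desaturation episodes**
with drops ≥ 3%, using drop/recovery phase logic on the signal's first
differences: a drop phase runs from the onset of decline to the nadir; the
recovery phase ends when SpO₂ returns to its pre-drop level, or — if it never
does — at the maximum SpO₂ within 2 minutes after the drop. Each episode's
**desaturation burden** is the area between the trace and its baseline (the
maximum SpO₂ in the 100 s before recovery onset):

    burden   = Σᵢ max(0, baseline − SpO₂ᵢ) / fs        [%·s]
    norm. burden = burden / episode duration            [%]

Seven overnight measures summarize each night:

| measure | definition |
|---|---|
| SpO₂ ENT | Shannon entropy of the SpO₂ value distribution (nats) |
| SpO₂ STD | population SD of the SpO₂ signal (%) |
| BAB | area below the overnight mean SpO₂ / analyzed time (%) |
| ODB AVG / STD / ENT | mean, SD, entropy of normalized episode burdens |
| NDB | cumulative episode burden / analyzed time (%) |

A cohort layer evaluates each measure as a predictor of postoperative
respiratory depression with L2-regularized logistic regression (covariates:
sex, BMI, cardiorespiratory comorbidity; class weights inverse to class
frequency), over 100 stratified 80/20 splits matched on sex, BMI, and outcome
prevalence, reporting mean AUC-ROC, sensitivity, and specificity with 95%
confidence intervals, plus Pearson correlations against reference severity
indices (e.g. the apnea–hypopnea index) with Fisher-transform intervals and a
sex-difference overlap test. Because the clinical cohort behind the method is
not public, a synthetic generator (`simulate_night()`, `simulate_cohort()`)
produces quantized 3 Hz nights and full cohorts with known ground truth.

## Worked example

```r
library(spo2burden)

cfg <- night_sim_config(duration_h = 8, event_rate_per_h = 25, seed = 42)
sim <- simulate_night(cfg)          # 8-h quantized 3 Hz night, known truth
pp  <- preprocess_spo2(sim$record)  # trim, mark invalid, median filter
pp$report
#> <preprocess_report> eligible (eligible); 450.0 min retained, 2.1% invalid

episodes <- detect_episodes(pp$record)
head(as.data.frame(episodes)[, c("onset_s", "nadir_s", "end_s",
     "drop_magnitude", "baseline_level", "burden", "normalized_burden")], 3)
#>    onset_s  nadir_s     end_s drop_magnitude baseline_level    burden normalized_burden
#> 1  45.0000  60.0000  68.33333              5             97  72.33333          3.100000
#> 2 160.3333 179.0000 195.00000              8             97 144.33333          4.163462
#> 3 232.3333 252.3333 279.66667              5             97 118.83333          2.510563

extract_features(pp$record)
#>   spo2_ent spo2_std   bab odb_avg odb_std odb_ent   ndb n_episodes analysis_duration_s
#> 1     1.38     1.59 0.529    2.63   0.695    3.19 0.821        175               26430
```

The night holds 175 episodes; the first drops 5% from a 97% baseline and
accumulates 72 %·s of burden over 23 s (normalized burden 3.1%, a mean depth
of ~3% below baseline). The overnight summary — entropy 1.38 nats, SD 1.6%,
NDB 0.82% — quantifies how much of the night is spent below baseline.

Correlation utilities work on any paired vectors:

```r
pearson_with_ci(c(1,3,2,5,4,7,6,9,8,10), c(2,3,4,4,6,6,7,9,10,11))
#> <spo2_cor> r = 0.927 [0.715, 0.983], n = 10 (strong)
```

A command-line front end wraps the same pipeline
(`inst/cli/spo2burden.R`, subcommands `features` / `simulate` / `evaluate` /
`correlate`).

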