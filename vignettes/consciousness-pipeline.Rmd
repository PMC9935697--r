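---
title: "Classifying consciousness from ICU vital signs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying consciousness from ICU vital signs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neurovitals)
```

# Overview

`neurovitals` classifies the behavioral level of consciousness of
neuro-ICU patients from routinely collected physiological signals. Daily
behavioral scores (0--5) are grouped into four categories -- coma (0),
VS/UWS (1), MCS− (2--3) and CF (4--5) -- and three binary tasks are
defined on them: VS/UWS vs MCS−, {coma, VS/UWS} vs {MCS−, CF}, and non-CF
vs CF. Each assessment is paired with the multivariate signal window
recorded **200 to 60 minutes before** it, and a gradient-boosted-tree
classifier is trained and evaluated under leave-one-patient-out (LOPO)
nested cross-validation. This vignette documents the model, every tunable
parameter, the numerical choices, and what the synthetic-cohort evidence
does and does not establish.

# The synthetic cohort generator

Because the clinical recordings the pipeline targets cannot be
redistributed, the package ships a generator whose output has the
statistical structure the analysis assumes. It is first-class, tested
code, not a test fixture.

**Signals.** Each signal is a discretized Ornstein--Uhlenbeck process
around a physiological baseline plus a slow sinusoidal component,
sampled every 5 s during a daily monitoring block:

$$x_{t+1} = x_t + \theta(\mu - x_t) + \sigma_s\,\varepsilon_t,\qquad
  y_t = x_t + A_s \sin(2\pi t / P),$$

with mean-reversion rate $\theta = 0.05$ per step, baseline $\mu$ and
noise scale per signal from `signal_specs()` (e.g. HR: 80 bpm baseline,
2 bpm innovation SD, 5-min period). Both the innovation SD $\sigma_s$ and
the periodic amplitude $A_s$ are scaled by the per-score multiplier
$1 + \text{effect\_size}\cdot s/5$ (`state_effect_multipliers()`), so
short-term variability *and* sample entropy increase monotonically with
the behavioral score $s$ -- the simulated analogue of the reduced
heart-rate variability and complexity reported in deepening coma. With
`effect_size = 0` the signals carry no information about the state; this
null setting is used as a leakage guard.

**Trajectories and assessments.** Scores follow a day-to-day first-order
Markov chain (stay probability `persistence = 0.6`, otherwise a step to
an adjacent score, reflecting at 0 and 5), initialized uniformly. No
within-day dynamics are claimed anywhere in the target setting, so the
chain is deliberately simple and its persistence is a free parameter, not
an estimate. One assessment per ICU day is drawn uniformly between 08:00
and 11:00; the per-patient number of days is normal with group-specific
means (SAH: 4.38 ± 2.86, ICH: 8.6 ± 2.89), truncated at one.

**Missingness.** Two mechanisms mirror the structure of real neuro-ICU
data: (i) whole-signal absence per patient, with group presets
(`default_absence_probs()`) taken from the documented rates -- TMP 43%/74%,
ICP 7%/88%, SPO2 7%/3%, HR 1%/0% for SAH/ICH; signals without a documented
rate default to 20% (invasive brain signals for ICH default to 95%, since
that group rarely has invasive monitoring); and (ii) contiguous in-series
gaps (`inject_missingness()`) with geometric run lengths (mean 24 samples
= 2 min) hitting an exact target fraction (default `gap_rate = 0.05`).

**What the generator does not emulate.** Cardio-respiratory coupling,
waveform-level structure, sedation effects, circadian rhythm, drift, or
sensor artefacts beyond range violations. A passing pipeline on synthetic
cohorts therefore demonstrates *correctness of the machinery* (no
leakage, recoverable signal recovered, honest null behavior), not
clinical performance on real recordings.

**Recording block.** Signals are simulated from 04:30 for 7 h daily
(`record_start_hour`, `record_duration_s`), which covers the
pre-assessment window for any assessment time in 08:00--11:00 without
simulating uninformative night-time data.

# Preprocessing

The stage order is fixed: **resample → impute → filter outliers →
window**.

- `resample_bins()`: non-overlapping 1-minute bins aligned to epoch
  minutes; bin value = arithmetic mean of in-bin samples (median via
  `window_config(agg=)`); empty bins are missing.
- `impute_lagged_knn()`: the series is detrended by its dominant Fourier
  component (single sinusoid, least squares at the periodogram peak of
  the linearly interpolated series); each interior missing point's
  residual pattern (10 lags each side) is matched by Euclidean distance
  against all fully observed patterns and filled with the mean of the
  `k = 5` nearest centre values, plus the sinusoid. Gap runs longer than
  `max_gap = 10` bins, edges, and fully missing series are never imputed,
  and observed values are never altered. This is a contract-level
  implementation of Fourier-assisted lagged k-NN imputation; the original
  algorithm's internals are not public, so numerical agreement with it is
  not claimed.
- `filter_outliers()`: inclusive clinical plausibility ranges per signal
  (`clinical_ranges()`; e.g. HR 20--220 bpm, MAP 20--200 mmHg), fully
  configurable. The exact clinical filter table used on the original data
  is not public; the defaults are deliberately permissive.
- `extract_window()`: the window is the **half-open** interval
  $[t-200\text{ min}, t-60\text{ min})$ -- 140 one-minute bins for any
  assessment time -- avoiding double-counting the boundary minute (no
  endpoint convention is stated in the target setting). A signal is
  *present* for a sample when ≥ 80% of its window bins are non-missing
  (`presence_min_frac`); the sample is *excluded* when the pooled missing
  fraction across all recorded signals exceeds 80%
  (`exclusion_missing_frac`). The presence rule is applied **after**
  imputation of short gaps but before feature extraction; whether it
  should precede imputation is genuinely open, and `max_gap` keeps the
  rule meaningful by leaving long gaps missing either way.

# Feature extraction

Each present signal window is denoised by a level-2 discrete wavelet
transform with the 8-tap Daubechies-4 filter (`denoise_dwt()`): an
orthonormal periodized decomposition, soft thresholding of all detail
levels at the universal threshold $\hat\sigma\sqrt{2\log n}$ with
$\hat\sigma$ the MAD of the finest details, exact reconstruction
otherwise. Interior gaps of ≤ 5 bins are linearly interpolated first;
longer residual gaps split the vector and features are computed on the
longest contiguous segment.

The default 16 features (`default_feature_set()`) span the temporal and
complexity domains: mean, median, SD, IQR, skewness, kurtosis, min, max,
root-mean-square of successive differences, lag-1 autocorrelation,
linear-trend slope, mean crossings, sample entropy (m = 2,
r = 0.2·SD), permutation entropy (order 3, normalized), Higuchi fractal
dimension (k_max = 8) and a low/high spectral power ratio (split at 0.1
cycles/bin ≈ 10-min periods). The exact feature list used on the original
data is not public, so this set is a documented, configurable default and
downstream results are feature-set-sensitive. Degenerate inputs return
defined values (constant series: SD 0, entropies 0, dimension 1, ratio 1)
rather than NaN. Columns are named `signal__feature`; all features of an
absent signal are missing for that row, and the variable subsets are
nested: `hospital` (HR, RR, SPO2) ⊂ `icu` (+ MAP, TMP, CO2EX) ⊂ `neuro`
(+ ICP, PbtO2, BrT; unavailable for ICH cohorts).

# Tasks and class weighting

`build_task_dataset()` keeps only the task's categories and labels the
**minority** side positive. The labeling convention is inferred, not
stated, in the target setting; it is the unique convention under which
every published no-skill AUPRC baseline equals the positive-class
prevalence of the corresponding category counts, and it is configurable
(`positive = "a"/"b"`). Training applies cost reweighting: samples of the
smaller class get weight (larger class size)/(smaller class size)
(`positive_weight()`).

# LOPO nested cross-validation

One round per patient; all of a patient's assessments are held out
together, so within-patient correlation never leaks across the split.
Per round:

1. **Signal matching.** Training columns are restricted to features of
   signals measured for the held-out patient, so train and test share a
   feature space.
2. **Feature selection** (optional, default off): top-N columns by gain
   importance of a preliminary fit, training data only.
3. **Tuning.** All combinations of gamma {0, 1}, min child weight
   {1, 5}, max depth {2, 4, 6}, learning rate {0.05, 0.1, 0.3} are scored
   by mean validation AUROC over **patient-grouped** inner 5-fold CV
   (sample-level folds would leak within-patient correlation) with early
   stopping (200 rounds max, patience 20). Ties break towards smaller
   depth, then smaller learning rate — the simpler model. The final model
   is re-trained on all training data with the mean early-stopped
   iteration count.
4. **Learner.** xgboost binary:logistic with native missing-value
   routing, single-threaded and seeded for determinism.

Rounds whose training data are single-class are skipped with a warning
and logged; rounds where inner tuning is impossible (every inner fold
single-class, only in tiny cohorts) fall back to the simplest grid
point. All rounds' predicted probabilities are **pooled** for evaluation
rather than averaging per-round AUROCs -- per-round AUROC is undefined
for single-class patients, and pooling uses every prediction once.

# Evaluation

All metrics are computed from the pooled probabilities:

- **AUROC** = P(random positive outranks random negative), ties ½
  (midranks); the reported curve's trapezoidal area equals it exactly.
- **DeLong 95% CI** via placement-value covariances (delegated to pROC);
  perfect separation degenerates to a zero-width interval with a warning.
- **Operating point**: Youden's J maximizer, ties broken towards higher
  sensitivity then lower threshold. The closest-to-(0,1) criterion is
  available via a flag; the two coincide on symmetric curves.
- **AUPRC** by step-wise precision--recall integration; the no-skill
  baseline is positive-class prevalence.
- **Calibration**: LOWESS (span 0.75, no robustness iterations, as the
  response is binary) of outcomes on probabilities, clamped to [0, 1];
  ICI = mean absolute curve-to-identity distance over samples, Emax = its
  maximum. At least 20 samples are required.
- **Signal relevance**: per round, features are ranked by gain importance
  (configurable in principle; rank-based, hence invariant to monotone
  transforms) and the top k = 5 taken; a signal counts once per round
  regardless of how many of its features appear. Relevance = rounds in
  top-k / rounds used; never-used signals are excluded (0/0).
- Multiple assessments of a patient are treated as exchangeable in the
  pooled metrics; no clustered-variance correction is applied, matching
  the pooling convention above.

# Problem sizes and statistical checks

The test suite validates the statistical machinery at sizes chosen to
give stable Monte-Carlo verdicts while keeping a full run in minutes on
one core: oracle equivalences (pair-counting AUROC, exhaustive threshold
sweeps, direct-count sample entropy) on ~100 randomized inputs of up to
200 samples; DeLong vs a 2000-replicate stratified bootstrap at
n = 1000 and coverage over 200 binormal simulations; end-to-end null
calibration (pooled LOPO AUROC within 0.5 ± 0.07, mean of 5 cohort
seeds) and strong-effect recoverability (AUROC ≥ 0.85) on 20-patient
hospital-subset cohorts with a reduced tuning grid (gamma 0, min child
weight {1, 5}, depth {2, 4}, learning rate 0.1, 60 rounds, 3 inner
folds). The reduced grid is a run-size choice for the synthetic checks;
the package default remains the full grid.

# Known limitations

- The generator's state effect enters through variability/complexity
  only; mean-level shifts, cross-signal coupling and sedation dynamics
  are absent, so feature families other than dispersion/entropy are
  exercised but not stressed.
- The imputation is a contract-level reconstruction; on real data its
  numeric output will differ from the original Fourier lagged k-NN
  implementation.
- The 16-feature set and clinical filter ranges are documented defaults,
  not the original supplementary tables.
- Published AUROCs on the original clinical cohorts are not reproducible
  here because those data are not deposited; the synthetic evidence
  establishes correctness, leakage-freedom and recoverability, not
  clinical effect sizes.
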