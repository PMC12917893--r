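---
title: "Methods: wearable-ECG HRV features and context-aware sequence modelling of NT-proBNP trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable-ECG HRV features and context-aware sequence modelling of NT-proBNP trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In persistent atrial fibrillation (AF) with heart failure, the biomarker
NT-proBNP tracks ventricular wall stress, but measuring it requires blood
sampling. Multi-day single-lead wearable ECG offers a continuous,
non-invasive window on the same physiology: although beat-to-beat
variability in AF no longer reflects sinus-node autonomic modulation,
long-window RR-interval statistics still carry information about global
autonomic tone and hemodynamic burden. `afbnp` implements the full chain
from device R-peak annotations to a patient-level prediction of the
6--12-month change in NT-proBNP:

1. quality gating and cleaning of R-peak streams,
2. 30-minute-window HRV features (time and frequency domain),
3. whole-recording RR/heart-rate summaries,
4. Yeo--Johnson + z-score standardization and tensor assembly,
5. a three-layer LSTM with context-aware attention and a regression head,
6. patient-level leave-one-out cross-validation (LOOCV) with RMSE, MAE
   and directional accuracy.

Because the clinical recordings that motivated this pipeline are not
public, the package ships a calibrated synthetic-cohort generator as a
first-class, tested module; every downstream stage is exercised against
it.

## The synthetic cohort generator

`simulate_cohort()` draws, per patient:

* **Clinical covariates** calibrated to the study population's baseline
  table: continuous variables are truncated-normal or log-normal with
  parameters solved from the published median/IQR (normal sd =
  IQR width / 1.349, log-normal sdlog analogously on the log scale);
  binary covariates are Bernoulli at the published prevalences. Baseline
  NT-proBNP is log-normal with median 1,344 pg/mL and sdlog 1.19 —
  deliberately heavy-tailed. Haemoglobin, platelets, uric acid and TR
  velocity have no published summaries; we use typical values for an
  elderly AF/HFpEF population (13.5 g/dL, 220×10³/µL, 5.5 mg/dL,
  2.5 m/s), chosen once.
* **A latent autonomic burden** `z ~ N(0, 1)`. It drives the RR
  dispersion (`110·exp(0.35 z)` ms, with a 5% log-normal residual
  nuisance) and the 0.1 Hz modulation amplitude (`22·exp(0.40 z)` ms).
  We model the burden as the *dominant* source of between-patient
  dispersion heterogeneity so that it is recoverable through the
  pipeline's own feature set (RMSSD-type and LF-type features); the
  residual nuisance represents measurement-scale variation only.
* **An AF-like R-peak stream**: successive intervals are shifted-gamma
  (floor 300 ms, mean and sd from the latent state) — an
  "irregularly irregular" i.i.d.-with-short-memory model — modulated
  multiplicatively by a 0.1 Hz component and a 24 h circadian component,
  rounded to integer milliseconds and clamped to [300, 2000] ms.
  Device noise is emulated as non-overlapping contiguous blocks with
  exponential lengths (mean 5 min) whose total length is exactly the
  configured fraction of the recording (2--10% by default).
* **The outcome**: `followup = baseline · exp(µ + β z + ε)` with β and
  the ε variance solved so the planted burden explains `effect_strength`
  of the log-ratio variance, total log-change sd 0.8 (roughly
  "halving to doubling" over 6--12 months, consistent with the wide
  dispersion of the biomarker in this population), and µ set from
  `direction_balance` (default 0.5, a neutral prior on
  increase vs decrease). The direction label is "increase" iff the
  change is strictly positive.

One user seed fans out to per-patient, per-purpose substreams through an
integer mixing function, so cohorts are bit-reproducible regardless of
the order in which pieces are generated.

A consequence worth stating explicitly: with `effect_strength = s`, the
best *achievable* directional accuracy of any predictor is
`0.5 + arcsin(√s)/π` (≈ 0.78 at s = 0.6), because the unexplained
fraction of the log-change is irreducible noise. End-to-end evaluations
on synthetic cohorts should be read against that ceiling, not against 1.

## Preprocessing conventions

* Noise intervals and analysis windows are half-open `[start, end)`;
  a peak exactly at an interval's end is kept. Overlapping noise
  intervals are merged on ingest.
* RR intervals are successive R-peak differences; each interval belongs
  to the 30-min window containing its *onset*, on a fixed grid anchored
  at the recording start. Windows are therefore disjoint and no interval
  is lost; the trailing partial window is kept and flagged.
* Plausibility bounds default to [300, 2000] ms (configurable), covering
  the AF ventricular response range; intervals outside are dropped
  without re-bridging the gap.
* A recording is usable iff merged noise covers ≤ 20% of the span *and*
  span − noise ≥ 48 h. "Unusable signal" is operationalized as
  noise-interval coverage, the only noise quantity the annotation model
  carries.

## HRV numerics

Time domain (per window): meanNN, SDNN (sample, n−1), RMSSD, NN50
(strictly > 50 ms), pNN50 = 100·NN50/(n−1).

Frequency domain: the tachogram is linearly interpolated at 4 Hz between
the first and last interval onset, mean-removed, and a Welch estimate is
formed from 5-minute Hann-tapered, linearly detrended segments with 50%
overlap. Band powers integrate the one-sided density over LF
0.04--0.15 Hz, HF 0.15--0.40 Hz and TP 0.0033--0.40 Hz. These follow
standard HRV practice; none are prescribed by the source data format,
and all are configurable.

Sentinels: a window is *valid* only when both families are computable —
at least two intervals and at least 5 minutes of interpolable tachogram.
Invalid windows carry −1 in all nine metrics, and the validity flag is
the single source of truth downstream: sentinel windows never enter
scaler statistics, are zero-filled after standardization, and receive
exactly zero attention weight. If HF is exactly zero (a degenerate,
essentially constant tachogram), LF/HF is also sentinelled, with a
warning, rather than returning ±Inf.

Whole-recording summaries (minRR/maxRR/avgRR, minHR/maxHR/avgHR via
HR = 60000/RR, and meanRMSSD over valid windows) span the *entire*
recording (3--7 days), following the convention that the "72 h" label
names the feature family, not a truncation.

## Standardization and tensor assembly

All features pass through a Yeo--Johnson power transform (λ by profiled
Gaussian maximum likelihood on [−3, 5]) followed by z-scoring — the
transform is fitted *before* the z-score, and both are estimated on the
training fold only. Zero-variance features are flagged and passed
through centred. The scaler state records the training patient ids and a
content hash, making leave-one-out hygiene auditable after the fact.

The per-patient model input is a T×F matrix (T = number of 30-min
windows, 144--336 for 3--7 days): the standardized HRV30min metrics,
two interaction terms (RMSSD × instantaneous HR, LF/HF × SDNN — products
of within-window metrics, declared defaults), and the standardized
static block (clinical metrics, RR and HRV72h summaries) replicated
across rows. The context vector is the standardized pair (baseline
NT-proBNP, meanRMSSD). Variable sequence lengths are handled by
tail-padding within a batch; padded and sentinel rows are masked, and
predictions are exactly invariant to appended padding.

## The model

Architecture: LSTM(64) → LSTM(32) → LSTM(16) → context-aware additive
attention → concat(pooled state, context) → dense(16, tanh, dropout) →
dense(1). Attention scores are
`e_t = vᵀ tanh(W_h h_t + W_c c + b)` — the minimal form in which a
static context vector modulates temporal weighting — with masked steps
scored −∞ so their softmax weights are exactly zero. The forward and
backward passes (full backpropagation through time) are implemented in
RcppArmadillo and verified against central finite differences in the
test suite.

Training: Adam (lr 0.001), batch size 8, MSE loss, L2 weight decay
0.001 on weight matrices, dropout 0.5 on the pooled attention output and
the head hidden layer (not on recurrent connections), early stopping on
the epoch-mean *training* loss with patience 10 (inside an LOOCV fold of
n−1 patients there is no validation split to monitor), best parameters
restored. Batches group patients of similar sequence length to limit
padding waste; batch order and in-batch order reshuffle every epoch. All
randomness (initialization, shuffling, dropout masks) derives from the
configuration seed.

Regression target: the standardized log ratio
`log(followup/baseline)`, inverted to pg/mL for reporting
(`Δ̂ = baseline · (exp(ŷ·s + m) − 1)`). We chose the log-ratio over the
raw pg/mL change because NT-proBNP is log-normal with sdlog ≈ 1.2 in
this population: raw deltas are dominated by a few high-baseline
patients and make a mean-squared objective numerically hostile, while
the log-ratio matches the multiplicative biology. The centre/scale are
estimated on the training fold and stored with the model.

## Evaluation

`loocv()` runs one fold per patient: scalers and model are fitted on the
other n−1 patients, the held-out change is predicted, and RMSE, MAE,
directional accuracy (label "increase" iff Δ > 0, exact zero counts as
decrease/stable) and absolute-error quartiles are aggregated. Per-fold
seeds derive from the configuration seed and the held-out patient's
rank, so folds reproduce independently of execution order. Each fold
records hashes of its scaler fit-population and training outcomes; the
test suite re-derives these from the id sets to prove the held-out
patient leaked into nothing. `permute_outcomes()` provides the label
permutation null; because scalers and tensors never touch the labels,
`prepare_loocv()` lets permutation replicates share one fold cache.

## Problem sizes used in the tests

The shipped test suite exercises the full study conditions — a 50-patient
cohort with 3--7-day recordings (seed 42, effect strength 0.6) — for the
end-to-end checks: LOOCV training uses an epoch cap of 30 (early
stopping usually engages near it), and the 10-permutation null uses 2
epochs per fold, where chance-level behaviour does not depend on
training length. Structural tests use smaller cohorts (4--6 patients,
3-day recordings) and reduced layer sizes; the architecture itself is
only ever shrunk in tests whose subject is a contract (masking,
determinism, serialization), never in the end-to-end evaluations.

## What the synthetic data does and does not show

The generator reproduces: the published baseline covariate distributions
at large n, irregularly irregular RR statistics with realistic beat
counts, device-style noise labelling, heavy-tailed NT-proBNP, and a
recoverable autonomic pathway with a controllable effect size. It does
**not** simulate waveform morphology (no P/QRS/T, no ectopy-vs-AF
distinction), non-stationary rate control (exercise, drug titration),
comorbidity-conditional outcome effects beyond the single planted
pathway, or informative missingness in follow-up timing. Passing
end-to-end tests therefore demonstrates that the pipeline is correct and
can recover a planted autonomic signal through the published feature
set at the stated effect size — not that the model would achieve any
particular accuracy on clinical data.

## Numerical details and edge cases

* Timestamps are integer milliseconds; RR round-trips through
  cumulative sums are exact.
* Empty RR series propagate as empty windows and sentinel features, not
  errors; an all-invalid patient is rejected with an
  `afbnp_insufficient_data` condition at tensor assembly.
* Welch segments shorter than the nominal 5 minutes fall back to a
  single segment of the available length; signals shorter than 8 samples
  are an input error (such windows are sentinelled earlier anyway).
* The Yeo--Johnson profile likelihood is optimized by golden-section
  search on λ ∈ [−3, 5]; features constant on the training fold skip the
  transform entirely.
* Non-finite training loss aborts with an `afbnp_training_divergence`
  condition, which LOOCV converts into a failed fold and an incomplete
  report rather than a crash.
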