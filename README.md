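# afbnp

Predicting 6–12-month NT-proBNP trajectories in persistent atrial
fibrillation (AF) from multi-day single-lead wearable ECG.

NT-proBNP is the standard blood biomarker of ventricular wall stress in
heart failure, but following it over time requires repeated blood
sampling. In persistent AF, conventional beat-to-beat HRV loses its
sinus-node interpretation, yet long-window RR-interval statistics still
reflect global autonomic tone and hemodynamic burden. `afbnp` implements
a complete, tested pipeline for turning device R-peak annotations into a
patient-level prediction of the NT-proBNP *change* over 6–12 months:

- **Preprocessing** — noise-interval cleaning (half-open `[start, end)`
  convention), RR computation, plausibility filtering ([300, 2000] ms),
  quality gates (≤ 20% noise, ≥ 48 h analyzable), 30-minute windowing on
  a fixed grid.
- **HRV features** — per window: meanNN, SDNN, RMSSD, NN50, pNN50 and
  Welch-spectrum band powers LF (0.04–0.15 Hz), HF (0.15–0.40 Hz),
  LF/HF, TP (0.0033–0.40 Hz) from the 4 Hz-resampled tachogram; per
  recording: minRR/maxRR/avgRR, minHR/maxHR/avgHR, meanRMSSD. Windows
  with insufficient data carry a `-1` sentinel in all nine metrics and
  are masked everywhere downstream.
- **Feature assembly** — Yeo–Johnson + z-score standardization (fitted
  on the training fold only), the published feature groups
  (`CM`, `RR`, `HRV72h`, `HRV30min`), interaction terms, replicated
  static block, and a context vector of baseline NT-proBNP and
  meanRMSSD.
- **Model** — LSTM(64) → LSTM(32) → LSTM(16) → additive attention whose
  scores are conditioned on the clinical context vector,
  `e_t = vᵀ tanh(W_h h_t + W_c c + b)`, then a two-layer regression
  head. Trained with Adam (lr 0.001), batch size 8, MSE on the
  standardized log-ratio target, dropout 0.5, L2 0.001, early stopping
  (patience 10). Forward/backward passes are hand-written in
  RcppArmadillo and verified against finite differences.
- **Evaluation** — patient-level leave-one-out cross-validation with
  RMSE, MAE and directional accuracy (increase iff Δ > 0), per-fold
  leakage hashes, a label-permutation null, and trajectory plots.
- **Synthetic cohort generator** — the original recordings are not
  public, so the package ships a generator calibrated to the study's
  baseline table (median age 70, 56% male, median NT-proBNP
  1,344 pg/mL, …) that plants a latent autonomic-burden signal linking
  RR dynamics to the outcome with a controllable effect size. All
  end-to-end tests run against it.

## Worked example

```r
library(afbnp)

cohort   <- simulate_cohort(cohort_config(n_patients = 8,
                                          recording_days_range = c(3, 4),
                                          effect_strength = 0.6,
                                          seed = 2024))
features <- extract_features(cohort)

dplyr::select(features$static, patient_id, age, baseline_bnp, avgRR, meanRMSSD)[1:4, ]
#>   patient_id   age baseline_bnp avgRR meanRMSSD
#> 1 P001        51.9         738. 1014.      78.4
#> 2 P002        78.0        1726.  678.     128.
#> 3 P003        58.8        1328.  763.     156.
#> 4 P004        65.9         339.  866.     211.

report <- loocv(features, model_config(max_epochs = 15, seed = 2024))
report
#> <cv_report> 8 folds | RMSE 751.63 pg/mL | MAE 574.82 pg/mL | directional accuracy 0.500
```

`features$static` holds one row per patient (clinical covariates plus
whole-recording summaries: `avgRR` in ms, `meanRMSSD` the mean RMSSD
over valid 30-min windows). `report` aggregates one LOOCV fold per
patient: `rmse`/`mae` are on the pg/mL change scale and
`directional_accuracy` is the fraction of patients whose predicted
change has the correct sign. At this deliberately tiny scale (7 training
patients per fold, 15 epochs) accuracy sits at chance — the packaged
test suite runs the same pipeline at the study scale (a 50-patient
cohort, epoch cap 30), where directional accuracy lands in the
0.70–0.78 range across cohort draws, a few points under the theoretical
ceiling for the planted effect size (see below). `tidy(report)` returns
the per-fold table, `glance(report)` the one-row metric summary, and
`autoplot(report, features$outcomes)` the observed-vs-predicted
trajectory plot.

Note that with a planted effect strength `s`, no predictor can exceed
directional accuracy `0.5 + arcsin(√s)/π` (≈ 0.78 at `s = 0.6`); see the
methods vignette (`vignettes/afbnp-methods.Rmd`) for the generator's
design and all numerical conventions.

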