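# eefusion

Personalized dynamic–static feature fusion for predicting energy
expenditure (EE, kcal/min) during incremental treadmill exercise from
wrist-worn tri-axial acceleration, ECG-derived RR-interval telemetry and
six static physiological traits.

## Who this is for

Researchers in exercise physiology and wearable sensing who want a fully
reproducible, end-to-end reference implementation of a multimodal EE
prediction pipeline — from raw sensor streams to interpretable models —
that runs entirely on synthetic cohorts with known generative structure,
so every stage can be validated by parameter recovery instead of against
private data.

## What it does

1. **Simulate** (`simulate_cohort()`): synthetic incremental-exercise
   sessions — RAMP protocol (3 km/h + 0.5 km/h per 30 s; stop at 90 % of
   220 − age or RER > 1.15), cadence-locked wrist acceleration at 10 Hz,
   lagged heart-rate/RR dynamics with intensity-dependent LF/HF structure
   at 1 Hz, VO₂/VCO₂ ramps at 0.1 Hz, plus injected spikes and dropouts
   with recorded ground truth.
2. **Clean** (`clean_session()`): Local Outlier Factor flagging on
   standardized (time, value) embeddings (k = 300 for acceleration, 30
   for RR), linear interpolation of flagged/missing samples, scalar
   random-walk Kalman smoothing.
3. **Featurize** (`featurize_session()`, `build_sequences()`): 10-s
   windows carrying 22 dynamic features (12 accelerometer: means, FFT
   total energies, mean amplitudes of X/Y/Z and the vector magnitude;
   10 ECG: mean RR, HRV band powers ULF/VLF/LF/HF, total/peak/mean
   spectral power, LF/HF ratio, heart rate), the treadmill speed, and the
   Weir-equation EE target `3.941·VO₂ + 1.106·VCO₂`; sequences of 10
   windows plus 6 static traits.
4. **Model** (`fit_ar()`, `build_fusion_model()`, `train_model()`): an AR
   linear baseline and dynamic–static fusion regressors (LSTM, and
   CNN+LSTM with channels 64/128, kernel 3, pool 2/stride 1, hidden 64,
   dropout 0.1, fusion width 32) trained with Adam (lr 0.001, batch 32,
   MSE), all in vectorized R with finite-difference-verified gradients.
5. **Evaluate** (`run_loso_experiment()`, `run_holdout_experiment()`):
   leave-one-subject-out cross-validation with per-fold normalizer refits,
   held-out-subject evaluation, RMSE/MAE/R² on normalized and kcal/min
   scales, Bland–Altman bias and limits of agreement.
6. **Explain** (`shap_values()`, `group_contribution_curve()`): Shapley
   attributions by expected gradients (exact linear attribution for AR),
   global top-k ranking, local feature–attribution Pearson relations by
   intensity bin (low 3–7.5, medium 7.5–11, high 11–15 km/h), and
   speed-stratified Acc-vs-ECG contribution curves with crossover
   detection.

## Worked example

```r
library(eefusion)

# a small homogeneous cohort, artifact-free for brevity
cohort <- simulate_cohort(
  cohort_params(n_subjects = 5, n_test = 1, seed = 42),
  noise = noise_params(outlier_rate = 0, missing_rate = 0))
seqs  <- featurize_cohort(cohort)
train <- subset_sequences(seqs, seqs$role == "train")
test  <- subset_sequences(seqs, seqs$role == "test")

rep <- run_holdout_experiment(train, test, arch = "cnn_lstm",
                              feature_set = "acc_ecg",
                              config = model_config(seed = 42),
                              epochs = 150)
print(rep)
#> <ee_eval_report holdout cnn_lstm/acc_ecg> n = 35
#>   R2 0.930  RMSE 0.062  MAE 0.051 (normalized)
#>   bias 0.007  LoA [-0.115, 0.129]
```

`R2` is the coefficient of determination of predicted vs true EE on the
held-out subject's sequences (EE min-max normalized on the training
range; `rmse_kcal`/`mae_kcal` in the report give kcal/min). `bias` and
`LoA` are the Bland–Altman mean difference (predicted − true) and its
95 % limits of agreement: the model over-predicts by 0.007 normalized
units on average and 95 % of its errors lie within about ±0.12 of that
bias.

Attribution of the trained model, over the whole cohort's sequences:

```r
nz  <- rep$model$normalizer
shp <- shap_values(rep$model, apply_normalizer(seqs, nz),
                   apply_normalizer(train, nz),
                   n_background = 20, n_steps = 30)
global_summary(shp, k = 3)$ranking
#>                feature mean_abs_shap rank
#> 1          rest_hr_bpm    0.04715229    1
#> 2     rest_vo2_mlkgmin    0.03483042    2
#> 3 R_Interval_MeanPower    0.03268348    3
curve <- group_contribution_curve(shp)
curve$crossover_kmh
#> [1] 12
```

On this deliberately tiny demo cohort the static resting traits and an
RR-interval spectral feature top the ranking, and the aggregated
ECG-feature contribution overtakes the acceleration contribution at
12 km/h. At the study scale (19 subjects), the detected crossover
concentrates around the 10.5 km/h dominance onset designed into the
generator — that recovery is exercised across ten seeded cohorts in the
test suite.

A full pipeline (simulate → clean → featurize → all model/feature
combinations → LOSO + holdout → attribution, with a run manifest) is one
call — `run_pipeline(default_config(), "out_dir")` — or from a shell via
the thin CLI `inst/cli/ee-fusion.R` (`simulate`, `preprocess`,
`featurize`, `train`, `evaluate`, `explain`, `run-all`).

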