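---
title: "Energy-expenditure prediction by dynamic-static feature fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-expenditure prediction by dynamic-static feature fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Energy expenditure (EE, kcal/min) during exercise is measured accurately by
indirect calorimetry — a gas analyzer tracking oxygen uptake (VO~2~) and
carbon-dioxide production (VCO~2~), combined through the abbreviated Weir
equation

$$\mathrm{EE} = 3.941\,\mathrm{VO_2} + 1.106\,\mathrm{VCO_2}
\quad [\mathrm{kcal/min},\ \mathrm{VO_2},\mathrm{VCO_2}\ \mathrm{in\ L/min}],$$

but gas analysis requires a face mask and a laboratory. Wearable sensors —
a wrist accelerometer and an ECG chest strap — are practical substitutes,
yet each alone degrades at some intensity: movement features saturate once
cadence and arm swing stop growing, while heart rate under-determines EE at
low intensity. `eefusion` implements a dual-branch regression that fuses
*dynamic* features (windowed accelerometer and RR-interval descriptors)
with *static* per-subject traits (height, weight, BMI, body-fat %, resting
HR, resting VO~2~), predicts EE over an incremental treadmill protocol, and
quantifies with Shapley values how the two modalities trade dominance as
intensity rises.

Because no public dataset accompanies this problem setting, the package
ships a synthetic-session generator as a first-class, tested module. All
empirical statements in this vignette are about that generator's output as
computed by the test suite and `scripts/acceptance.R`; none are claims
about any private dataset.

## The synthetic cohort

`simulate_cohort()` draws subjects from the cohort trait distributions
(defaults: height 169.89 ± 8.42 cm, weight 63.41 ± 11.74 kg, body fat
16.89 ± 6.68 %, resting HR 59.74 ± 7.09 bpm, resting VO~2~ 3.69 ± 0.76
ml/kg/min; BMI is recomputed from height and weight rather than drawn, so
profiles are internally consistent). Ages are uniform on 18–25 years; the
default cohort is 19 subjects, the last 4 labelled as the held-out test
set.

Each subject runs a RAMP-style protocol: 3 km/h, +0.5 km/h every 30 s,
terminated when heart rate reaches 90 % of the age-predicted maximum
(220 − age) or the respiratory exchange ratio (RER) exceeds 1.15, with a
hard cap at 15 km/h. The termination time is rounded up to the next gas
sample so all streams end on a common 10-s boundary.

The three measured streams are generated as:

* **Acceleration (10 Hz, g).** Each axis is a cadence-locked sinusoid:
  frequency $f(s) = 1.2 + 0.1 s$ Hz, amplitude $a(s) = 0.2 + 0.08 s$ g
  scaled by axis gains (x 1.0, y 0.6, z 0.35) and a per-subject arm-swing
  gain $\sim N(1, 0.15)$, riding on a constant gravity projection, plus
  white noise (sd 0.02 g). The phase is the integral of the instantaneous
  cadence, so speed steps cause no discontinuities. The cadence
  coefficients keep $f$ below the 5 Hz Nyquist limit at 15 km/h; configs
  violating that bound are rejected.
* **RR intervals (1 Hz, s).** Heart rate follows a first-order lag (time
  constant 30 s) toward a target rising from resting HR to 220 − age as
  speed approaches the subject's aerobic-fitness speed
  ($\sim N(12.5, 1.0)$ km/h). The paper-thin published description of HR
  kinetics pins only the endpoints; the first-order lag is the simplest
  model producing realistic ramp kinetics. RR = 60/HR plus zero-mean HRV
  jitter built from an LF tone (0.1 Hz) and an HF tone (0.3 Hz) — both
  exactly bin-centred for 10-sample windows — whose variance split shifts
  linearly toward LF with speed (equal split at the crossover speed), and
  whose total sd (0.05 s at rest) shrinks by 70 % at top speed, mirroring
  exercise HRV suppression.
* **Gas exchange (0.1 Hz, L/min).** VO~2~ starts at the resting value
  (ml/kg/min × weight / 1000) and rises with a speed-scheduled mixture of
  the movement envelope (normalized swing amplitude, including the
  subject's gain) and the lagged relative heart rate:
  $w_{ECG}(s) = \mathrm{clip}\!\left(\tfrac12 + \tfrac{s - s_\times}{2\,\delta},\,0,\,1\right)$
  with crossover $s_\times = 10.5$ km/h and ramp half-width $\delta = 4.5$
  km/h. Below the crossover the movement drive carries more weight; above
  it the cardiac drive does. This is the *designed* ground truth that the
  attribution stage is later asked to recover. VCO~2~ = RER × VO~2~, with
  RER ramping linearly from 0.80 past the 1.15 termination threshold at
  the fitness speed.

Artifacts (amplitude spikes at 5–8× the local swing envelope, ectopic-like
RR spikes of ±0.3–0.6 s, and dropped samples) are injected at configurable
rates (defaults 1 % spikes, 0.5 % missing) and their indices recorded in
the session ground truth, so cleaning recall is measured exactly rather
than estimated.

What the generator does *not* emulate: raw ECG waveforms (the 1 Hz stream
is beat-interval telemetry, which is also what chest straps export),
biomechanically faithful gait, treadmill incline, breath-by-breath gas
noise, day-to-day variability, or any drift/nonstationarity beyond the
protocol ramp. Tests passing on this generator therefore demonstrate that
the pipeline recovers *known* structure of the designed kind — not that
the models would reach the same accuracy on field recordings.

## Cleaning

Per stream, `clean_session()` applies:

1. **Local Outlier Factor** on the series embedded as standardized
   (time index, value) points — pure value-space LOF cannot flag
   contextual spikes whose value is plausible elsewhere in the ramp.
   Neighborhood sizes default to one protocol step: k = 300 (30 s at
   10 Hz) for acceleration, k = 30 for RR. The implementation is the
   classic k-distance / reachability / density-ratio construction with an
   exact windowed neighbor search (points outside a time window are
   provably farther than the in-window k-distance, with brute-force
   widening as fallback); it matches a direct O(n²) reference to
   floating-point accuracy in the tests. Duplicate points with zero
   k-distance are handled by capping the local reachability density at
   10¹².
2. **Interpolation**: samples with LOF score above 1.5 (a conventional
   inlier/outlier boundary; exposed in config) and originally missing
   samples are linearly interpolated, edges held. Because density scores
   are biased upward at series boundaries (the steep heart-rate onset has
   no left-hand context and scores ~2 despite being perfectly good data),
   the flag bar is doubled within the first and last k samples; genuine
   spikes score well above it.
3. **Kalman smoothing** with a scalar random-walk state. Both cleaned
   streams use high-gain defaults (q = 10⁻¹·var, r = 10⁻²·var,
   steady-state gain ≈ 0.95): the accelerometer's cadence band
   (1.2–2.7 Hz of a 5 Hz Nyquist) and the RR series' HRV bands
   (0.04–0.4 Hz of a 0.5 Hz Nyquist) both sit close to their Nyquist
   frequencies, and a low-gain smoother would annihilate exactly the
   oscillations the feature bank measures (a gain-0.1 filter passes only
   ~16 % of a 0.1 Hz LF tone at 1 Hz sampling). The smoother therefore
   shaves residual white noise; spike removal is LOF's job. On noiseless
   sessions the pass is near-identity (the tests bound the perturbation),
   which is the behaviour a smoothing stage should have when there is
   nothing to remove. Low-gain settings remain available through the
   configuration for genuinely slow trend streams.

Gas and speed streams pass through untouched; they are reference
measurements, not noisy wearables. Cleaning never changes stream lengths
or timestamps, and every sample is flagged `original` or `interpolated`
with counts in the provenance log.

## Feature bank

`featurize_session()` produces one window per gas sample whose trailing
10 s are fully covered (the t = 0 sample has no history, so a session of
T seconds yields T/10 windows). The 22 dynamic features are:

* 12 accelerometer features: window means of AccX/AccY/AccZ and the
  vector magnitude VM = √(x²+y²+z²); FFT total energies (mean-removed,
  Σ|X~k~|²/N, equal to the time-domain sum of squared deviations by
  Parseval — asserted to 10⁻⁹ in the tests); mean amplitudes (mean
  absolute deviation; 2A/π for a sinusoid of amplitude A).
* 10 ECG features: mean RR; periodogram band powers over the standard HRV
  bands ULF (≤ 0.003 Hz), VLF (0.003–0.04], LF (0.04–0.15], HF
  (0.15–0.4]; total power; peak frequency; mean power; LF/HF ratio; mean
  heart rate from the device channel.

Numerical choices worth stating:

* On a 10-sample window the spectral resolution is 0.1 Hz, so ULF and VLF
  are below resolution and identically zero. They are computed per the
  band definitions and kept for fidelity to the feature bank; models see
  them as constants (the normalizer assigns unit scale with a warning).
* The periodogram's Nyquist bin (0.5 Hz) lies outside every HRV band.
  Total power is therefore defined as the integral over (0, 0.4] — the
  HF ceiling — so the four bands partition it exactly; peak frequency
  searches all positive bins. Mean power is total power divided by the
  number of in-range bins.
* LF/HF with an empty HF band returns the finite sentinel 0 rather than
  infinity, keeping feature matrices finite.
* Windows are trailing and non-overlapping (stride = one gas sample);
  overlap enters only at the sequence level, where 10 consecutive windows
  slide with stride 1. A window mean is used for AccX/Y/Z (the 10 × 22
  sequence shape requires one value per feature per window), and
  HeartRate averages the device HR channel rather than recomputing
  60/mean(RR).

`build_sequences()` assembles samples of 10 consecutive windows × 22
features plus the 6 static traits, targeted on the final window's EE.
`fit_normalizer()` z-scores dynamic and static features and min-max scales
the EE target to [0, 1], using training subjects only; the transform is
invertible and evaluation reports both scales. Headline metrics are on the
normalized scale, which is the scale on which sub-0.1 RMSE values are
meaningful for this task; kcal/min values accompany them.

## Models

Three families, all consuming the same sequence samples:

* **AR baseline** — ordinary least squares of the target on the 10 lagged
  dynamic-feature vectors flattened (10·d + 1 coefficients; lag order 10
  matches the sequence length). No static inputs, by definition. A
  rank-deficient design falls back to ridge (10⁻⁶) with a warning.
* **LSTM fusion** — an LSTM (64 hidden units) over the 10-step sequence;
  the final hidden state, after dropout 0.1, is concatenated with the
  static branch (dense width 32, ReLU), passed through a dense fusion
  layer (width 32, ReLU) and a linear scalar head.
* **CNN+LSTM fusion** — two valid 1-D convolution blocks along the time
  axis (channels 64 then 128, kernel 3, ReLU, max-pool size 2 stride 1)
  before the same LSTM and fusion head. With no padding the sequence
  length contracts 10 → 8 → 7 → 5 → 4; the recurrent layer consumes the
  length-4 convolution output and its final hidden state feeds fusion.

Training is Adam on MSE, batch size 32, learning rate 0.001, a fixed epoch
budget (no early stopping), Glorot-uniform initialization with forget-gate
bias 1. One master seed drives initialization and batch shuffling, making
runs bit-reproducible. Forward and backward passes are authored in
vectorized R and verified against central finite differences (including
input gradients) in the test suite. Because batches are drawn by shuffling
sample indices, stochastic-gradient training is order-sensitive by
construction; order-invariance of *predictions* holds exactly, and
order-invariance of *fits* is asserted for the closed-form AR model.

Where the published architecture description left choices open, the
package fixes them as follows: valid (no-padding) convolutions; the
LSTM's final hidden state (not the cell state or the full sequence) feeds
fusion; the static branch width equals the printed fusion width (32);
dropout applies to the recurrent output only.

## Evaluation

`run_loso_experiment()` implements leave-one-subject-out cross-validation:
per fold, the normalizer is refit on that fold's training subjects only —
refitting per fold is the only leakage-free reading of "features were
normalised" — the model trains at the per-fold budget (500 epochs by
default) and is scored on the held-out subject; the report carries the
per-fold table and mean ± SD, the layout used for cross-validated
comparisons of (architecture × feature set). `run_holdout_experiment()`
retrains once on all training subjects (1500 epochs by default) and scores
the pooled held-out test subjects, adding Bland–Altman agreement
(differences are predicted − true; bias ± 1.96 × SD limits). RMSE, MAE and
R² follow the standard definitions; RMSE ≥ MAE and the null predictor's
R² = 0 are asserted as properties.

## Attribution

`shap_values()` uses expected gradients (path-integral attribution
averaged over a training background set) for the differentiable models:
kernel-style exact Shapley estimation is infeasible on 10 × 22 sequence
inputs, while the path method preserves the completeness axiom that makes
the group curves meaningful. For the linear AR model the exact Shapley
values of a linear function (coefficient × displacement from the
background mean) are used. Per-time-step attributions are summed per
feature — summation is the aggregation that preserves additivity — and
completeness (base + Σ attributions = prediction) is checked for every
explained sample at a 2 % tolerance relative to the largest explained
deviation in the batch; violations are errors, not warnings. Features
outside a model's feature set receive exactly zero attribution (the
null-player axiom, asserted structurally).

Global importance ranks features by mean |attribution| (top 15 by
default). Local analysis pairs each feature's values with its attributions
and reports their Pearson correlation, with samples tagged by the
intensity bins low [3, 7.5), medium [7.5, 11), high [11, 15] km/h.

`group_contribution_curve()` aggregates |attributions| of the 12
acceleration features and the 10 ECG features per 0.5 km/h speed bin (the
protocol increment), min-max standardizes each group's curve across bins
(z-score optional), and reports the crossover speed: the lower edge of the
lowest bin at which the ECG curve reaches the acceleration curve *and
stays at or above it in every later occupied bin*. The persistence
requirement prevents noise-triggered declarations at the dip each curve
shows near its background mean. Bins with fewer than 5 samples are treated
as unoccupied: with 0.5 km/h bins a sparser bin average is dominated by
one or two sequences and would distort both the standardization range and
the crossover search (top-of-ramp bins are reached by few subjects). A
group with no attribution mass standardizes to 0, not 0.5, so a model that
ignores a modality yields a first-bin crossover rather than an artificial
tie.

## Problem sizes and test design

The test suite and the acceptance script run everything end-to-end at
sizes chosen for a single CPU: 19-subject cohorts (15 train / 4 test, the
default split), sessions of ~8–11 minutes as produced by the default
termination criteria, ~40–60 sequence samples per subject, and reduced
epoch budgets (around 100 epochs for recovery experiments, against the
500/1500 defaults) — reported as scaled-down operating points, with the
full budgets remaining the configuration defaults. Structure-recovery
checks (fusion beating single-modality and AR baselines; crossover
detection within ±1 km/h of the designed 10.5 km/h) are evaluated as
majorities over ≥ 10 independent seeds, because individual seeds at this
scale are genuinely variable.

## Known limitations

* The generator's EE is a smooth deterministic function of speed, HR and
  subject traits; real calorimetry adds breath-by-breath noise and
  kinetics (VO~2~ slow component) that the models never see here.
* The two modalities are correlated through speed by construction;
  attribution splits between correlated informative inputs are a property
  of the trained network, and the crossover estimate inherits that
  variability (hence the majority-over-seeds framing).
* ULF/VLF features are structurally zero at the native window length;
  they are retained for schema fidelity, not information.
* LOSO at 500 epochs × 15 folds × 9 model/feature combinations is
  expensive in plain R; the defaults are faithful, but practical runs on
  one CPU should reduce epochs or the grid via the configuration.
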