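---
title: "Decoding gait from surface EMG: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding gait from surface EMG: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gaitdecode` implements a surface-EMG (sEMG) motion decoder for walking:
it selects an informative muscle subset from activation dynamics,
classifies the four gait phases (initial contact IC, flat foot FF, heel
off HO, toe off TO) from windowed time-domain EMG features with an LSTM,
predicts the ankle angle 40 ms ahead of time by coupling EMG, phase and
the current angle, and adapts a trained decoder to the
signal-distribution shift induced by exoskeleton assistance via
fine-tuning. Everything is exercisable on a bundled synthetic gait
simulator, so the full pipeline is testable without any recording.

## The activation model

Raw sEMG is band-passed (20–450 Hz, 4th order), notch-filtered at the
mains frequency, full-wave rectified, normalised by the peak rectified
value and low-pass filtered (4 Hz, zero phase) into an envelope
$e(i) \in [0, 1]$. The corner frequencies are conventional values for
surface EMG; only the processing *steps* are fixed by the method, so all
cutoffs sit in `activation_params()`.

Neural activation follows the second-order recursion

$$u(i) = \alpha\, e(i - d) - \beta_1 u(i-1) - \beta_2 u(i-2),$$

with the electromechanical delay $d$ (default 40 ms, rounded to whole
samples) and coefficients parameterised through the filter poles:
$\beta_1 = \gamma_1 + \gamma_2$, $\beta_2 = \gamma_1 \gamma_2$ with
$|\gamma_i| < 1$ for stability, and $\alpha - \beta_1 - \beta_2 = 1$ so
a sustained envelope drives $u$ to the same level (unit DC gain). Both
constraints are enforced at construction, never at run time. Muscle
activation applies the nonlinear shape map

$$a = \frac{e^{A u} - 1}{e^{A} - 1}, \qquad A \in [-3, 0],$$

with $A = -2$ by default; $A = 0$ is handled by its analytic limit
$a = u$. The recursion coefficients have no canonical published values —
they are meant to be fit by least squares against a reference trace — so
the defaults $\gamma_1 = \gamma_2 = -0.5$ simply sit well inside the
stability region, and `fit_activation_params()` performs the grid-seeded
bounded search. What the reference trace should be is left to the caller
(it is an explicit argument), because the calibration signal is a
property of the experiment, not of the model.

## Muscle selection

For each muscle, $a(t)$ is integrated over every phase segment of every
complete gait cycle (trapezoidal rule; a cycle runs between TO→IC
transitions) and averaged across cycles, giving per-phase areas $A_i$.
Normalising each muscle's areas by its own maximum yields effects
$E_i \in [0, 1]$ with row maximum exactly 1. The selection rule
formalises "similar activation in at least three phases": a muscle is
discarded when at least three of its four phase effects have another
phase of the same muscle within `delta = 0.15`; a coverage pass then
re-adds the discarded muscle with the highest effect in any phase whose
best retained effect falls below 0.6, so the four phase-dominant muscles
always survive. On the bundled nine-muscle effect table for level
treadmill walking this retains exactly `{RF, TA, ST, GM, GL}`, and the
subset is stable for `delta` anywhere in roughly `[0.06, 0.19)`.
Comparisons carry a `1e-9` tolerance so boundary cases are not decided
by floating-point noise. Note the rule is *within-muscle* flatness, not
between-muscle redundancy: TA and ST have nearly identical rows yet both
stay, which is what makes the formalisation non-obvious.

## Features and windows

Sliding windows of 180 ms advance in 40 ms steps (rounded to samples:
200 and 44 at 1111.11 Hz). Each window yields the four standard
time-domain features per channel — mean absolute value, zero crossings,
slope sign changes, waveform length — concatenated to a $4n$-dimensional
vector. ZC/SSC amplitude thresholds default to 0 and are exposed because
hardware noise floors differ. Features are computed on the band-passed
raw signal (standard myoelectric practice), not on the activation
envelope. Window phase labels are majority votes; windows straddling
transitions keep their majority label, and classification errors
concentrate there by construction.

## The networks

Both models are many-to-one sequence networks over 10 consecutive
windows (400 ms of context; the context length has no published value —
one cycle third is enough to disambiguate cycle position without making
training sequences scarce). The phase classifier is
LSTM(40)–LSTM(40)–dense(20, ReLU, dropout 0.5)–softmax(4). The angle
predictor couples a feature extractor, LSTM(30)×3 + dense(5, ReLU),
applied to the EMG features, with a predictor stack,
LSTM(30)–LSTM(30)–dense(60, ReLU, dropout 0.5)–dense(1); the gait phase
(one-hot by default, ordinal optional) and the current angle join as
side channels at the predictor's first LSTM rather than passing through
the 5-unit extractor bottleneck — squeezing the angle through five ReLU
units measurably cripples every EMG-carrying mode. In `angle_only` mode
the extractor is dropped entirely. Dropout is applied after fully
connected hidden layers but not after the 5-unit projection (halving a
five-unit code destroys it).

The LSTM stack, backpropagation through time, and the optimiser are
implemented in RcppArmadillo (`src/lstm.cpp`). A test verifies the
analytic gradients against central finite differences through the full
stack, including the side-channel bypass. Training uses Adam with
decoupled weight decay (default `1e-3`), global gradient-norm clipping
at 5, minibatches of 64, and early stopping on a *time-ordered tail*
validation split — a randomly interleaved split would correlate with the
training sequences and mask temporal overfitting. All randomness
(initialisation, shuffling, dropout) flows from one integer seed, so
fixed-seed training is bit-reproducible on one machine. Because
successive windows overlap by 140 of 180 ms, adjacent training sequences
are near-duplicates; `train_config(stride = k)` thins them for the heavy
experiments at little information cost. Prediction always uses every
window, warm-starting sequences shorter than the context length by
repeating the first window.

Fine-tuning continues training *all* weights at a reduced learning rate
(default `1e-4`) on the first $m$ minutes of shifted-condition data
(1 min = 1500 windows at the 40 ms increment). The budgets are
cumulative: each step carries over the previously adapted model and
trains it on the enlarged data window, mirroring a protocol in which
one more minute of assisted data is added and the decoder updated —
and making the adaptation curve intrinsically stable, since the model
only gains exposure. Every budget is evaluated on the same fixed
held-out tail — the windows beyond the largest budget — rather than on
the shrinking remainder, so points on the adaptation curve are
comparable.

## What the simulator emulates

`generate_trial()` produces one multi-rate recording: sEMG at
1111.11 Hz, two foot-switch channels at 500 Hz, one joint angle at
100 Hz, with stream lengths `floor(duration × rate)`.

* **Cycle schedule.** Cycle durations are truncated-normal
  (mean 1.1 s, CV 5%); each cycle splits into IC/FF/HO/TO with fractions
  0.10/0.35/0.30/0.25. The four-phase split has no published numeric
  values, so these are conventional gait proportions.
* **Activation bursts.** Per muscle and phase, raised-cosine bursts with
  compact support (width = phase duration, so per-cycle burst area is
  exactly `gain × width / 2` — chosen over Gaussians precisely so the
  phase-area tests have a closed form). Bursts sit early in their phase
  (onset + 30% of the phase width): activation must *lead* the events it
  drives, otherwise the electromechanical delay carries no usable
  information. Default gains follow the typical lower-limb pattern
  (quadriceps in early stance, plantarflexors in late stance, TA and
  hamstrings around swing).
* **Raw sEMG.** Envelope × band-limited (20–450 Hz) unit-variance
  Gaussian carrier, plus 1% sensor noise.
* **Stride-to-stride variability.** Per cycle and phase, one amplitude
  factor (CV 0.35) and one timing offset (SD 30 ms, clamped at 2.25 SD)
  scale and shift *both* the bursts and the angle keyframes they drive.
  Surface-EMG burst amplitudes genuinely vary this much between strides;
  this shared modulation is the mechanism by which the EMG announces the
  upcoming kinematics.
* **Angle trace.** Eight keyframes per cycle (phase onsets and
  mid-phases, sketching an ankle dorsi/plantarflexion cycle with a
  heel-strike dip and a push-off plantarflexion swing) define a
  zero-order-hold drive smoothed by a causal two-stage exponential
  filter (τ = 20 ms, group delay compensated), plus smoothed
  measurement noise (0.3°). Causality here is load-bearing: a global
  interpolating spline would bend toward future keyframes and leak them
  into the angle history, at which point angle-only extrapolation
  becomes unbeatable and the EMD structure is decorative. With the
  zero-order hold, nothing about an event is visible in the angle before
  it fires, while the leading EMG has already announced it.
* **Electromechanical delay.** The envelope evaluates the gait schedule
  `emd_ms` (default 40 ms) ahead of the mechanical clock, so the
  envelope leads the angle; a fixed-seed test verifies that changing the
  EMD moves the envelope-angle cross-correlation peak by exactly the
  difference.
* **Foot switches.** Heel contact during IC+FF, forefoot contact during
  FF+HO, plateaus plus 5% Gaussian noise — thresholding must be
  non-trivial but reliable. `label_phases_from_fsr()` recovers labels by
  thresholding at a fraction of each trace's maximum and merges runs
  shorter than 20 ms into their longer neighbour.
* **Exoskeleton condition.** `default_exo_shift()` models powered
  plantarflexion assistance: the assisted plantarflexors (SL, GM, GL)
  drop to 60% of their drive (assistance reduces calf effort), bursts
  arrive 40 ms later (a systematic recruitment-timing change, one window
  increment, clearly outside the stride-to-stride jitter), and IC
  duration shrinks by 20%. An earlier, milder shift (+30% gain, +15 ms)
  proved indistinguishable from the calibrated stride-to-stride
  variability — per-channel standardisation absorbs gain changes and a
  15 ms delay hides inside 30 ms timing jitter — so it could not produce
  the cross-condition degradation it exists to model.

What the simulator does **not** model: motor-unit physiology, ground
reaction forces, multi-joint coupling, electrode lift-off or sweat
artifacts, inter-subject anatomy. Passing tests on this generator shows
the pipeline correctly exploits the statistical structure the decoder
assumes (phase-locked bursts, EMD lead, shared stride variability,
condition shifts); it does not certify accuracy levels on real
recordings.

## Experiment conditions and problem sizes

The behavioural test suite fixes these study conditions:

* *Phase classification*: one 170 s trial; the first 2 minutes of
  windows train, the remainder tests; 20 epochs. Held-out accuracy
  exceeds 0.90.
* *Input ablation*: four 200 s training trials and one 200 s test trial
  (multi-trial training mirrors the leave-one-trial-out protocol, and
  the ordering of input modes only emerges in a multi-trial data
  regime); 30 epochs, sequence stride 2, batch 96; the median over five
  training seeds of the coupled (EMG + phase + angle) predictor's RMSE
  lies below the angle-only model's.
* *Degradation and recovery*: a 240 s unassisted trial against a 330 s
  assisted trial; adaptation budgets of 1–4 minutes, evaluated on the
  fixed tail beyond 4 minutes; classifier epochs 20, fine-tuning
  12 epochs at learning rate `1e-4`. Across five training seeds the
  within-condition ceiling exceeds the cross-condition accuracy by at
  least 5 points, the median adaptation curve is non-decreasing, and
  the 4-minute budget closes to within 2 points of the ceiling.

These sizes are the package's chosen desk-scale conditions; the
human-subject accuracy levels of treadmill studies (ten subjects,
8-minute trials) are not reproducible from synthetic data and are not
asserted anywhere.

## Numerical choices and degenerate inputs

* Stream lengths truncate (`floor`), window counts follow
  `floor((n − L)/I) + 1`, ms-to-sample conversions round.
* Phase-area integrals extend each trapezoid one sample to the right so
  a constant activation integrates exactly to the phase duration.
* The NRMSE denominator is the *predicted* trace's range, following the
  method's stated (if unusual) convention; a reference-range variant
  sits behind `use_reference_range = TRUE`.
* The Pearson metric uses the population convention consistently (the
  choice cancels) and refuses constant inputs; NRMSE refuses a constant
  prediction; ANOVA is the closed-form between/within mean-square ratio
  (cross-checked against `aov()` in the tests) and refuses groups
  smaller than two.
* Ties in the coverage-repair step break by input order; selection is
  otherwise permutation-consistent.
* All-zero EMG raises "peak is zero" rather than producing NaN;
  all-zero foot-switch traces raise "no contacts detected".
* `fine_tune()` refuses budgets that exceed the available data, and a
  degenerate (constant) reference in `fit_activation_params()` returns
  the defaults with a warning.

## Known limitations

* The LSTM engine is CPU-only, single-threaded, and deliberately small:
  layer kinds are limited to LSTM and dense, many-to-one losses only.
* The leave-one-out driver treats one feature frame as one trial; it
  does not manage subject-level covariates.
* The envelope-correlation property holds for muscles whose bursts are
  broad relative to the 4 Hz envelope low-pass; very narrow bursts
  (short-phase muscles) are smoothed and correlate lower — visible in
  the generator defaults, and a caution transferable to real IC-phase
  muscles.
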