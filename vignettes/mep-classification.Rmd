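---
title: "Classifying motor-evoked potentials by muscle: models, simulation design and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying motor-evoked potentials by muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During intraoperative neuromonitoring (IONM), motor-evoked potentials (MEPs)
are elicited by electrical stimulation of the motor cortex and recorded with
needle electrodes in target muscles. A mislabeled recording channel can mask a
true warning sign, so an automatic check that a trace labeled *abductor
pollicis brevis* actually looks like an APB response is a genuine safety
mechanism. `mepmuscle` implements such a check as a four-class classification
problem over two upper-extremity muscles (extensor digitorum, EXT; abductor
pollicis brevis, APB) and two lower-extremity muscles (tibialis anterior, TA;
abductor hallucis, AH), together with the explainability layer needed to
understand *why* a model assigns a muscle.

Every recording is a 2000-sample trace: 100 ms at 20 kHz, with the stimulus
at time zero and a stimulation artifact occupying the first 20 ms.

## The synthetic cohort generator

Clinical MEP archives are not redistributable, so the package ships a
generator whose output has the statistical structure the analysis relies on,
making every downstream stage testable from code alone. Each simulated MEP is
a Gaussian-enveloped sinusoid:

* the carrier frequency is the muscle's *main frequency*, drawn from
  N(300, 65) Hz for proximal muscles (EXT, TA) and N(450, 65) Hz for distal
  muscles (APB, AH): distal responses carry higher frequency content, but the
  per-muscle distributions overlap substantially, as clinical main-frequency
  distributions do. The 65-Hz SD is deliberate: with a tighter spread
  (SD 40 Hz) frequency becomes a cleaner separator than latency ever is in
  real recordings, and the feature-attribution structure inverts (frequency
  would outrank latency). Latency distributions, in contrast, separate
  cleanly between extremities;
* the burst starts at the *onset latency*, drawn per muscle from
  N(22, 2) ms (EXT), N(24, 2) ms (APB), N(37, 3) ms (TA), N(40, 3) ms (AH).
  Latencies are truncated below at 20 ms so the response begins after the
  excluded artifact window. Upper-extremity latencies are shorter than
  lower-extremity ones, and within one limb the distal muscle is slightly
  later than the proximal one, reflecting conduction distance;
* the burst contains `n_phases` full carrier cycles (3-5, uniform), is
  truncated at the final zero crossing (so the waveform stays continuous) and
  is shaped by a Gaussian envelope with sigma equal to half the burst length.
  The flat envelope is deliberate: with a narrower envelope (sigma = burst/3)
  the first carrier lobe has prominence close to the 2 x SD peak-detection
  threshold and the first detected peak becomes unstable, which no real
  preamplified MEP shows;
* each patient carries one multiplicative amplitude factor, log-uniform in
  [0.5, 2], plus mild within-patient trial-to-trial variability
  (log-normal, sigma 0.15); additive white noise has SD 0.05 in unscaled
  units, and a decaying oscillatory stimulus-artifact transient (amplitude 3)
  occupies only the first 400 samples;
* recordings from center "T2" have every latency shifted +3 ms, emulating a
  second center with different stimulation practice;
* class proportions default to EXT 31.8%, APB 42.9%, TA 15.7%, AH 9.6% — a
  realistic supratentorial-surgery case mix — so class weighting
  is genuinely exercised; 8% of recordings are noise-only traces with no MEP.

The default cohort is 200 patients with 13 recordings per patient per muscle
slot (apportioned over muscles by the class mix), about 10,400 MEPs of which
roughly 8,000 survive preselection. The shifted-center test cohort has 60
patients. These sizes keep a full four-model run on one CPU in the tens of
minutes while leaving per-class counts in the hundreds on the validation side.

What the generator does **not** emulate: polyphasic late components, anesthetic
fade, electrode drift, 50-Hz interference, inter-muscle crosstalk, or any
dependence of amplitude on muscle identity. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline recovers structure *of the kind
designed into the generator* — they are software verification, not clinical
validation, and no accuracy measured on simulated cohorts says anything about
accuracy on clinical recordings.

## Preselection

A recording contains an MEP when, after dropping the first 400 samples:

1. at least one peak with topographic prominence >= 2 x SD of the trace is
   found;
2. the duration — end latency minus onset latency — is below 40 ms;
3. the interval between first and last peak is below 35 ms.

Onset latency is 1 ms *before* the trace first leaves the band
`baseline mean +/- SD`, where the baseline is the final 5 ms and the SD is the
population SD of the artifact-stripped trace; the end latency mirrors this
from the other end, with the 1-ms shift applied outward so the
onset-end interval brackets the burst. Three conventions were genuinely open
and are fixed here: (a) the whole-trace SD is computed on the artifact-stripped
1600 samples, since including the artifact would make the threshold
artifact-dominated; (b) "crossing" means leaving the band in either direction;
(c) the preselection peak detector reuses the feature extractor's 2 x SD
prominence rule, so both modules share one peak definition. All derived
statistics are scale-invariant, so preselection is unaffected by amplifier
gain.

## Representations

**Time.** A linear-phase FIR band-pass (30-1000 Hz, 1601-tap Hamming
windowed-sinc) applied with group-delay compensation, so the overall response
is zero-phase and latencies are not shifted; then each trace is divided by the
maximum absolute value over *all* of its patient's traces. 1601 taps put the
10-Hz rejection beyond 20 dB while keeping the FFT-convolution cheap; the
low transition is still soft, which is acceptable because MEP energy lives two
octaves above the low edge.

**Features.** Five predictors per filtered, normalised trace: first prominent
peak latency (first rather than largest, matching clinical onset-proximal
usage), maximum signal value, number of prominent peaks, main frequency (DFT
magnitude argmax at the raw 12.5-Hz bin resolution, no zero padding), and mean
first derivative per millisecond. A correlation screen utility documents that
the five stay mutually uncorrelated (|r| < 0.6) on default cohorts.

**Time-frequency.** The magnitude of a Mexican-hat continuous wavelet
transform at 224 logarithmically spaced scales from 2 to 30 (center
frequencies ~2.5 kHz down to ~170 Hz at 20 kHz sampling), with the time axis
decimated from 1600 samples to 224 columns by nearest-index selection:
a 224 x 224 scalogram. The transform is evaluated by direct convolution at
the 224 retained columns only, which is exact and avoids computing the 1376
discarded columns.

## Models

Four families, all emitting a 4-probability vector in the fixed order EXT,
APB, TA, AH, all trained with inverse-frequency class weights
(`N / (4 * count_c)`) and patient-stratified splits (70% of recordings into
training by whole patients; no patient on both sides):

* **rf_feature / rf_time** — probability random forests (`ranger`).
  Hyperparameters come from a documented grid searched on an inner
  patient-stratified split: trees {100, 200} x mtry {2, 3} x minimum node
  size {5, 25} for the 5-feature input, and a lean grid (150 trees,
  mtry {40, 200}) for the 1600-dimensional input, where a wide grid would
  dominate a single-CPU run without changing the conclusions.
* **cnn1d** — two strided 1D convolutions (16 and 32 filters, kernel 9,
  strides 4 and 2), max pooling, dropout 0.3, batch normalisation, a dense
  layer of 64 and a softmax output. Strides replace full-resolution
  convolutions to keep one epoch over ~5600 traces in seconds on a CPU.
* **cnn2d** — scalograms are block-averaged 8 x 8 to 28 x 28, then four
  convolution + batch-norm blocks (8/16/32/32 channels, 3 x 3 kernels, same
  padding) with max pooling after blocks two and three, global max pooling
  after block four, and a dense softmax output; hyperparameters fixed, no
  tuning.

The CNN engine is implemented in the package itself (im2col convolutions via
BLAS, Adam, class-weighted cross-entropy, early stopping on a patient-disjoint
15% monitor slice with patience 5, learning rate 1e-3, batch 64, up to 30
epochs for the 1D and 10 for the 2D network). All randomness — initialisation,
shuffling, dropout — flows through R's seeded RNG, so training is exactly
reproducible for a given seed. Classification uses a confidence threshold:
the argmax class is emitted only when its probability reaches the threshold
(chance level 0.25 never abstains); sweeping the threshold to 0.9 trades
retention for accuracy.

## Evaluation

Accuracy is the primary metric, complemented by 4 x 4 confusion matrices,
confidence-retention curves over thresholds 0.25-0.90 (step 0.05), and the
dispersion of per-muscle accuracies (SD in percentage points and
CV = 100 x SD / mean, with both SD and mean on the percent scale). Bicentric
feature differences use the classic pooled-variance Student t test per muscle
at alpha = .05, with no multiple-testing correction (the number of tests is
reported instead); its type-I error is verified by simulation. The
shifted-center cohort probes domain shift: the +3 ms latency shift pushes TA
latencies into the learned AH territory, so test accuracy drops below
validation accuracy without collapsing — the qualitative bicentric pattern.

## Explainability

* **Impurity importances** are recomputed from the forest structure: per-tree
  Gini decreases weighted by in-bag node covers, normalised per tree, then
  averaged (mean and SD across trees).
* **Shapley attributions** use the exact path-dependent polynomial-time
  algorithm for tree ensembles, implemented in C++ against the ranger tree
  structures with in-bag covers. Exactness is enforced two ways in the tests:
  local accuracy (base value plus attributions equals the predicted
  probability to 1e-6) and agreement with a brute-force Shapley enumeration
  on small trees. Attributions are computed on a 20% simple-random subsample
  of the training set with a logged seed. On default cohorts the mean
  |attribution| ranks peak latency first and main frequency second, with low
  latencies pushing toward upper-extremity classes and high frequencies
  toward distal classes — exactly the generator's discriminative axes.
* **Grad-CAM** maps come from the gradients of a class logit with respect to
  the activation following the last convolutional layer (the canonical target
  choice), channel-averaged into weights, rectified, and upsampled (linear to
  1600 samples; bilinear to 224 x 224). Per-muscle averages of 2D maps are
  summarised by a mass-based lower bound: the smallest scale at which the
  cumulative time-marginalised attention reaches a quarter of the total. A
  mass bound captures how far down in scale attention extends and is robust
  to where the profile peaks (a relative-to-maximum threshold is dominated by
  the peak location instead). Distal muscles bound at smaller scales (higher
  frequencies) than proximal ones.

## Numerical conventions and degenerate inputs

* SD means population SD (divisor n) throughout the preselection and
  prominence rules.
* Argmax ties (DFT bins, class probabilities) resolve to the first index /
  fixed class order.
* A trace that never leaves the detection band has undefined onset/end and is
  not an MEP; an all-zero patient group cannot be normalised and raises a
  degenerate-input error; a constant feature column yields NA correlations,
  reported as such.
* Zero-variance t-test input is reported as undefined rather than silently
  dropped.

## Limitations

The generator's independence assumptions (frequency independent of latency
within muscle, amplitude independent of class) make the synthetic task easier
than the clinical one; accuracies on synthetic cohorts are upper bounds of
nothing clinical and should be read only as pipeline verification. The 2D
network sees 28 x 28 pooled scalograms, so its attention maps have coarse
scale resolution (7 x 7 before upsampling). The bicentric shift is a pure
latency translation; real center effects also involve montage, anesthesia and
stimulation differences that no single offset captures.
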