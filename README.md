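# mepmuscle

Muscle classification of intraoperative motor-evoked potentials (MEPs), with
explainable models.

During intraoperative neuromonitoring, MEPs from four routinely monitored
muscles — extensor digitorum (EXT) and abductor pollicis brevis (APB) in the
arm, tibialis anterior (TA) and abductor hallucis (AH) in the leg — are
recorded as 100-ms, 20-kHz traces. Identifying the muscle from the signal
alone provides a safety check against channel mislabeling. `mepmuscle`
implements the full analysis pipeline for this task on synthetic bicentric
cohorts (clinical MEP archives are not redistributable):

1. **Simulation** — labeled cohorts of Gaussian-enveloped sinusoid bursts with
   muscle-specific onset latencies (upper < lower extremity) and main
   frequencies (distal > proximal), per-patient amplitude scales, a +3 ms
   latency shift for the second center, imbalanced class proportions
   (31.8 / 42.9 / 15.7 / 9.6 %), stimulus artifacts and noise-only traces.
2. **Preselection** — a recording contains an MEP iff at least one peak with
   prominence ≥ 2 × SD is detected, its duration (end − onset latency) is
   < 40 ms, and the first-to-last-peak interval is < 35 ms; onset latency is
   1 ms before the trace leaves the band *baseline mean ± whole-trace SD*.
3. **Representations** — 30-1000 Hz zero-phase FIR filtering with per-patient
   normalisation; five engineered features (peak latency, maximum value,
   number of peaks, DFT main frequency at 12.5-Hz resolution, mean slope);
   224 × 224 Mexican-hat wavelet scalograms (scales 2-30, log-spaced).
4. **Classification** — probability random forests on the time and feature
   representations, a 1D CNN on traces and a 2D CNN on scalograms (CNNs
   implemented in-package on base-R matrix algebra), with inverse-frequency
   class weights `N/(4·n_c)`, patient-disjoint 70/30 splits, and
   confidence-threshold abstention from chance level 0.25 up to 0.9.
5. **Evaluation** — accuracy, confusion matrices, confidence-retention
   curves, per-muscle dispersion (SD, CV), and pooled-variance Student
   t tests comparing feature means across centers per muscle.
6. **Explainability** — impurity importances recomputed per tree, exact
   path-dependent tree Shapley attributions (local accuracy to 1e-6), and
   Grad-CAM attention maps for both CNNs with per-muscle averaging.

## Worked example

```r
library(mepmuscle)

report <- run_experiment(list(seed = 2026))  # the default study conditions
print(report)
#> <run_report>
#>   accepted labeled recordings: 7687 (train+validation), 2253 (test)
#>   rf_feature validation 0.882 | shifted-center test 0.845
#>   rf_time    validation 0.875 | shifted-center test 0.804
#>   cnn1d      validation 0.880 | shifted-center test 0.836
#>   cnn2d      validation 0.879 | shifted-center test 0.802
```

Reading: of 11,400 simulated training-center recordings, 7,687 pass the MEP
preselection rule and carry a muscle label. Each model family classifies
held-out patients of the training center with ~0.88 accuracy (chance is
0.25) and loses accuracy on the shifted-center test cohort — the +3 ms
latency shift moves TA responses into learned AH territory — without
collapsing, mirroring the qualitative bicentric degradation. The report also
holds confusion matrices, confidence-retention curves, per-muscle dispersion,
and the explainability layer:

```r
report$xai$rf_feature$shap_global
#>                       feature    mean_abs      sd_abs
#> peak_latency     peak_latency 0.199379011 0.155716307
#> main_frequency main_frequency 0.178867644 0.142141925
#> slope                   slope 0.011821187 0.013354652
#> max_value           max_value 0.005485269 0.010014647
#> n_peaks               n_peaks 0.001509966 0.002500877
```

Peak latency dominates the attributions, followed by main frequency — the two
axes the generator encodes — with short latencies pushing predictions toward
arm muscles and high frequencies toward distal muscles.

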