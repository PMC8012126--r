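---
title: "Recognizing the impulse of love at first sight from ECG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing the impulse of love at first sight from ECG: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgilfs)
```

## The problem

The impulse of love at first sight (ILFS) is a fast, involuntary affective
response to a potential partner. Like other emotional states it leaves a
physiological trace: excitement raises heart rate and shifts the balance of
autonomic control, which is visible in the beat-to-beat variation of the
RR intervals of an electrocardiogram. `ecgilfs` implements a complete
recognition pipeline for this state from single-lead ECG recorded during a
picture-viewing paradigm: subjects view 10-second stimuli, report the
induced ILFS intensity (0--3) plus arousal, valence, dominance and
attraction on 1--7 Likert scales, and the pipeline classifies each trial as
ILFS or non-ILFS from 25 heart-rate-variability (HRV) features.

Because studies of this kind rarely deposit raw recordings, the package
ships a first-class synthetic study generator with per-trial ground truth,
so every stage — from waveform to cross-validated accuracy — is testable
without any external data.

## Pipeline overview

1. **Synthesis** (`generate_study`): trial-structured ECG plus self reports.
2. **Preprocessing** (`downsample`, `denoise_dwt`, `segment_trials`):
   200 Hz, wavelet soft-threshold denoising, 10-s trial windows.
3. **R-peak detection** (`pan_tompkins`, `to_rr`): RR series per trial.
4. **Features** (`extract_features`): 25 HRV descriptors per trial.
5. **Dataset** (`screen_and_label`, `mad_filter`, `build_dataset`):
   rating-based labels, 5-MAD outlier removal.
6. **Selection and evaluation** (`sffs`, `nested_cv`, `run_experiment`):
   floating feature selection inside nested 10-fold cross-validation,
   five classifiers, Se/Sp/F1/AUC/ACC.

## The synthetic study generator

The generator's defaults are the study conditions assumed throughout the
tests. Each trial's tachogram is

$$RR_i = \mu + a_{LF}\sin(2\pi\,0.1\,t_i) + a_{HF}\sin(2\pi\,0.25\,t_i) + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma_{RR}^2),$$

evaluated at the cumulative beat time $t_i$ and clipped to the
physiological range 300--2000 ms. The two sinusoids sit at the centers of
the LF (0.04--0.15 Hz) and HF (0.15--0.4 Hz) spectral bands so that every
frequency-domain feature has signal to find. The ILFS class has its mean
RR shortened by `delta_rr`; this is the direction reported for the state
(higher heart rate under excitement). The waveform places a Gaussian-bump
P-QRS-T template (R amplitude 1 mV) at each beat time and adds white
measurement noise; true beat times are returned as ground truth.

Defaults and why:

* `fs = 1000` Hz, `trial_duration = 10` s — the acquisition conditions of
  the emulated paradigm.
* `mean_rr_non = 800` ms (75 bpm), a typical resting young-adult rate;
  `delta_rr = 80` ms, a clearly detectable but physiologically moderate
  acceleration (~8 bpm).
* `sdrr = 30` ms, `lf_amp = 20` ms, `hf_amp = 10` ms — resting short-term
  HRV magnitudes in the range commonly reported for healthy students.
* `noise_sd = 0.05` mV — 5% of the R amplitude, a clean laboratory
  recording.
* Ratings: ILFS trials draw intensity from {2, 3} and Likert dimensions
  from $N(6, 1)$; non-ILFS trials intensity 0 and $N(2, 1)$; rounded and
  clipped to the scale. Conditional-on-class Gaussian noise is the
  simplest model that exercises the screening logic.

What the generator does **not** emulate: ectopic beats and arrhythmia,
respiration-coupled morphology change, electrode motion artifacts,
between-subject baseline differences, and ordinal rating biases. Passing
tests therefore demonstrate correctness of the algorithms under the
stated statistical structure, not field performance on real recordings.

## Preprocessing choices

* **Downsampling** 1000 → 200 Hz: 8th-order Butterworth low-pass at 80%
  of the output Nyquist, run forward-backward (zero phase) over an
  odd-symmetric reflection padding to suppress edge transients, then
  decimation. Event times are kept in seconds and are unaffected.
* **Wavelet denoising**: periodized orthonormal db4 decomposition of the
  whole recording, depth $\lfloor \log_2 f_s \rfloor$ (7 levels at
  200 Hz), so the coarsest approximation spans 0--0.78 Hz and can be
  zeroed to remove sub-1-Hz baseline drift without touching ECG content.
  Detail coefficients are soft-thresholded. Two numerical choices matter
  and were made after direct experiments on clean synthetic ECG:
  * the noise scale $\sigma$ is estimated from the **finest** detail
    level only ($\sigma = \mathrm{MAD}(d_1)/0.6745$). Per-level MAD at
    coarse levels — where coefficient vectors are short and
    signal-dominated — reads the waveform itself as noise and flattens
    the P and T waves (clean-signal correlation drops to ~0.33);
  * the threshold is the **minimax** rule
    $\lambda = \sigma(0.3936 + 0.1829\log_2 N)$ rather than the universal
    $\sigma\sqrt{2\ln N}$. The universal rule's larger shrinkage biases
    the sparse, large QRS coefficients enough that denoising *increased*
    RMSE at 10 dB SNR; minimax restores a strict improvement while
    keeping the clean-signal correlation above 0.999.
* **Order**: denoise first, then segment, so no 10-s window carries
  decomposition edge artifacts; segments are exact slices of the denoised
  recording, cut at the nearest sample to the stimulus onset.

## R-peak detection

`pan_tompkins` follows the classic stage chain with its reference
constants: 5--15 Hz band-pass (zero-phase), five-point derivative
(centered, zero-phase variant), squaring, 150-ms moving-window
integration, dual adaptive thresholds with running signal/noise peak
estimates, a 200-ms refractory period, and search-back at 1.66x the
running RR average (last eight accepted intervals). Thresholds initialize
from the first two seconds (signal estimate max/2, noise estimate
mean/2). Because only 10-s windows are available, detection runs per
segment and RR statistics use all beats so far in the window. Accepted
integration peaks are refined to the band-passed maximum and finally to
the raw-signal maximum, and intervals outside (200, 3000) ms are screened
out.

## The 25 HRV features

Features follow their standard definitions; conventions that are
genuinely open were fixed as follows and are tested against brute-force
oracles:

* Sample (n−1) variance everywhere, including the Poincaré axes, so the
  identities $SD1 = SDSD/\sqrt2$ and $SD1^2 + SD2^2 = 2\,SDRR^2$ hold
  exactly (mixing conventions would break one of them).
* `Mean_HR` is the mean of instantaneous rates $60000/RR_i$, not
  $60000/\overline{RR}$; by Jensen's inequality the two differ, and the
  instantaneous mean is what "average heart rate over beats" means.
* `QD` is the semi-interquartile range $(Q_3 - Q_1)/2$ with
  linear-interpolation quantiles.
* CSI/CVI/modified CSI use the standard Toichi/Jeppesen forms via the
  ellipse axes $T = 4\,SD1$, $L = 4\,SD2$: $CSI = L/T$,
  $CVI = \log_{10}(LT)$, $mCSI = L^2/T$. A constant series has $SD1 = 0$;
  the ratio indices are returned as `NA` and such trials are dropped at
  dataset assembly.
* `LZC` binarizes the RR series at its median (≥ median → 1), parses with
  the LZ76 exhaustive history, and normalizes $c(n)\log_2(n)/n$ — the
  dominant convention for HRV complexity. The classic test sequence
  0001101001000101 parses to 6 phrases (0|001|10|100|1000|101).
* Frequency features use the Lomb–Scargle periodogram on the raw
  (beat time, RR) pairs without resampling: a 10-s window holds too few
  beats for spline-resampled Welch estimates. Band powers integrate the
  density over 0.04--0.15 Hz (LF), 0.15--0.4 Hz (HF) and their union
  (TP); the shared grid node at 0.15 Hz makes TP = LF + HF exact. A
  10-s window cannot resolve 0.04 Hz — one cycle lasts 25 s — so the LF
  edge is under-resolved by construction; the convention is kept as the
  analysis defines it, and this limitation should be remembered when
  interpreting LF-based features on single trials.

## Labels, outliers, dataset

A trial is labeled ILFS iff its reported intensity is 2 or 3 **and** all
four Likert dimensions are ≥ 5; non-ILFS iff intensity is 0 **and** all
dimensions ≤ 3; everything else, including every intensity-1 trial, is
excluded. The cut-offs sit symmetrically around the scale midpoint 4 and
are configurable; whether intensity 2 belongs in the ILFS class is
genuinely ambiguous, so `keep_intensity` exposes it.

Outlier removal uses the 5-MAD band with closed bounds (a point exactly
at median ± 5 MAD is removed, as the rule is written). The scope is the
most conservative reading of sample removal: the mask is computed per
feature within each class, and a trial flagged on any feature is dropped
entirely. When MAD = 0 the rule is degenerate and removes nothing (a
warning is emitted) — this protects near-constant count features such as
NN50 from wiping out a class.

## Feature selection and evaluation

`sffs` is the standard floating form: inclusion adds the feature
maximizing the cross-validated accuracy criterion $J$; conditional
exclusion then repeatedly removes the least useful feature whenever the
reduced subset strictly beats the best known subset of that size and the
feature is not the one just added. The printed Step-2 condition of some
descriptions ("if the removed feature is the most important in the new
set") is self-referential; the well-defined Pudil formulation above is
what is implemented. $J$ ties break toward the lowest feature index;
every subset is evaluated at most once (cached); the accuracy curve over
subset sizes 1..k_max and the full trajectory are returned.

`nested_cv` keeps selection honest: SFFS sees only the outer training
folds (inner 10-fold criterion), the classifier refits on the outer
training set restricted to the selected subset, and metrics pool over the
outer test folds. Corrupting a fold's held-out labels cannot change the
subset selected for that fold — this is asserted by direct experiment in
the test suite.

Classifier defaults (all overridable via `params`): SVM with RBF kernel
(C = 1, gamma = 1/d on standardized features), random forest with 100
trees, Gaussian naive Bayes, kNN with k = 5 (odd, so two-class votes
cannot tie), and a gini decision tree with cp = 0 and depth cap 30.
Features are standardized with training-fold statistics only. ILFS is the
positive class, so sensitivity measures ILFS detection. Pooled-over-folds
confusion counts are the primary metric basis; AUC is the rank-based
(Mann–Whitney) area over the continuous scores.

The per-feature group comparison uses the two-sided rank-sum
(Mann–Whitney) test: the two groups are independent sets of trials, so
the unpaired form matches the data structure; a paired signed-rank
variant is available behind `paired = TRUE` for matched designs.

## Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` run on sizes chosen to give
stable statistics at desk scale: studies of 10 subjects x 20 trials (200
trials, ~100 after screening), 10 simulation seeds for calibration
checks, 20 instances for the SFFS-versus-exhaustive comparison (8
features, all 255 subsets enumerated), and SFFS depth k_max = 2 inside
the null-calibration nested CV and k_max = 6 in the acceptance script —
deep enough to exercise the floating step while keeping the roughly
10^4 classifier fits of a nested run affordable. Null calibration
(delta_rr = 0) must land at chance accuracy for every classifier in both
modes; an 80-ms effect must be recovered through the full signal path
within ±10 ms and classify at ≥ 0.85 accuracy.

## Known limitations

* The generator's class effect is a free parameter: the emulated study
  reports no effect sizes, so simulated accuracies say nothing about the
  accuracy attainable on real recordings.
* All trials share one baseline heart rate per class; there is no
  between-subject variance component, and cross-validation splits by
  trial, not subject (a `fold_id` argument allows subject-wise splits if
  grouping is required).
* LF-band features on 10-s windows are under-resolved (above).
* The Pan–Tompkins refinement assumes upright R waves, as rendered by
  the template; inverted-lead recordings would need a polarity check.
* SFFS is a heuristic. The test suite verifies by enumeration that it
  never falls below greedy forward selection, but it does not — and
  cannot — guarantee the exhaustive-search optimum at every subset size:
  on small problems the empirical "optimum" of a cross-validated
  accuracy criterion is an extreme-value statistic over all subsets, and
  at sizes away from its search trajectory SFFS visits only a handful of
  candidates. Subset-size-by-size optimality claims should therefore be
  read as approximate.
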