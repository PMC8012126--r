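# ecgilfs

Recognition of the impulse of love at first sight (ILFS) from single-lead
ECG.

## What this package does

The ILFS — the fast, involuntary attraction response to a potential
partner — is an affective state with a measurable cardiac signature:
excitement raises heart rate and shifts autonomic balance, which shows up
in the beat-to-beat variability of the RR intervals. `ecgilfs` implements
an end-to-end pipeline that classifies 10-second ECG trials as ILFS or
non-ILFS:

1. **Synthetic study generator** — trial-structured ECG (Gaussian-bump
   P-QRS-T template on a sinusoid-plus-noise tachogram) with per-trial
   self reports (ILFS intensity 0–3; arousal/valence/dominance/attraction
   1–7) and full ground truth, so the whole pipeline is testable without
   any external recordings.
2. **Preprocessing** — downsampling to 200 Hz, wavelet (db4) denoising
   with soft thresholding and sub-1-Hz baseline removal, 10-s trial
   segmentation at stimulus onsets.
3. **R-peak detection** — the Pan–Tompkins algorithm (band-pass,
   derivative, squaring, 150-ms integration, dual adaptive thresholds,
   200-ms refractory, search-back), yielding the RR series per trial.
4. **25 HRV features** — 12 time-domain (Mean_RR, CVRR, SDRR, RMSSD, MSD,
   SDSD, NN50/pNN50, NN20/pNN20, Mean_HR, QD), 7 nonlinear (Poincaré
   SD1/SD2/SD1_SD2, CSI, CVI, modified CSI, Lempel–Ziv complexity) and 6
   frequency-domain (Lomb–Scargle band powers TP/LF/HF, LF/HF, nLFP,
   nHFP).
5. **Dataset construction** — rating-based labeling (ILFS: intensity
   ∈ {2,3} and all four Likert dimensions high; non-ILFS: intensity 0 and
   all dimensions low; intensity-1 trials excluded) and 5×MAD outlier
   removal per feature within class.
6. **Feature selection and evaluation** — sequential floating forward
   selection (SFFS) maximizing a cross-validated accuracy criterion,
   nested inside stratified 10-fold cross-validation; five classifiers
   (SVM, random forest, naive Bayes, kNN, decision tree); sensitivity,
   specificity, F1, rank-based AUC and accuracy; per-feature Mann–Whitney
   rank tests.

Poincaré indices use the ellipse axes T = 4·SD1, L = 4·SD2 (CSI = L/T,
CVI = log10(L·T), mCSI = L²/T); LZ complexity is the LZ76 phrase count of
the median-binarized RR series normalized by n/log2(n). The methods
vignette (`vignettes/ilfs-ecg-pipeline.Rmd`) documents every convention
and design choice.

## Worked example

```r
library(ecgilfs)

cfg <- simulation_config(n_subjects = 6, trials_per_subject = 20,
                         delta_rr = 12, seed = 42)   # weak 12 ms effect
study <- generate_study(cfg)
#> Synthetic ILFS study: 6 subjects x 20 trials (10 s at 1000 Hz), 60 ILFS / 60 non-ILFS

features <- suppressWarnings(run_pipeline(study))    # full signal path
dataset  <- suppressWarnings(build_dataset(features, study$ratings))
#> ILFS dataset: 68 trials x 25 features (35 ILFS, 33 non-ILFS)
#> removed: 28 excluded by screening, 0 missing, 24 MAD outliers

fa <- feature_analysis(dataset$X[dataset$y == 1, ], dataset$X[dataset$y == 0, ])
head(fa[order(fa$p_value), 1:3], 3)
#>  feature      p_value significant
#>  Mean_HR 7.291497e-06        TRUE
#>  Mean_RR 2.421629e-05        TRUE
#>       QD 1.148125e-01       FALSE

run_experiment(dataset, "without", seed = 1)
#> Classifier evaluation (no feature selection):
#>  classifier     Se     Sp     F1    AUC    ACC
#>         svm 0.7143 0.6667 0.7042 0.7697 0.6912
#>          rf 0.7143 0.6667 0.7042 0.8203 0.6912
#>          nb 0.6571 0.7273 0.6866 0.7844 0.6912
#>         knn 0.6857 0.6667 0.6857 0.6965 0.6765
#>          dt 0.5714 0.6667 0.6061 0.6918 0.6176

sffs(dataset$X, dataset$y, "rf", k_max = 6, seed = 1)
#> SFFS (rf): best J = 0.8382 at k = 4, subset {4, 12, 17, 22}; 141 J evaluations
```

Reading the output: the injected 12-ms RR shortening is picked up most
strongly by Mean_HR (higher under ILFS) and Mean_RR (lower), the five
classifiers reach 62–69% cross-validated accuracy on all 25 features, and
SFFS finds a four-feature subset (RMSSD, QD, CVI, HF) whose inner
cross-validated accuracy is 0.84. With the default 80-ms effect the
classes separate almost perfectly; with `delta_rr = 0` every classifier
stays at chance — both calibrations are asserted in the test suite.

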