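# sarcscreen

Analysis pipeline for sarcopenia screening from coupled wearable-sensor
recordings: surface electromyography (sEMG) and piezoelectric strain
captured simultaneously over the brachioradialis (BR) and flexor
digitorum superficialis (FDS) muscles during maximal voluntary grip
contractions (MVCs). It is aimed at biomedical-signal and
wearable-sensing researchers who want a complete, tested reference
implementation of this analysis — from raw multichannel time series to a
cross-validated, interpretable classifier — plus a physiologically
grounded simulator to run it on.

## What the package computes

**Ground truth** comes from the AWGS-2019 screening rule: low skeletal
muscle index (SMI < 7.0 kg/m² men, < 5.7 women) together with low
handgrip strength (< 28 kg men, < 18 women) or poor five-times
chair-stand performance (>= 12 s) defines sarcopenia.

**Feature engineering** extracts nine descriptors per analysis window
from the sEMG channels — six Hudgins time-domain features

    RMS  = sqrt(mean(x_i^2))        MAV = mean(|x_i|)
    iEMG = sum(|x_i|) * dt          WL  = sum(|x_{i+1} - x_i|)
    ZC   = sign changes > eps       SSC = slope-sign changes > eps

and three Morlet-wavelet features (absolute power, kurtosis of the
coefficient magnitudes, and wavelet entropy of the scale-energy
distribution). Features are normalized to the mean of the three MVC
trials per subject and read at the end of the hold phase, where
fatigue-driven compensatory activation separates the groups.

**Classification** uses a three-stream CNN–LSTM fusion network (raw
4-channel windows -> two convolution blocks -> LSTM; engineered features
and demographics each lifted by an affine map; concatenated into a dense
softmax head), written in plain R with hand-written backpropagation and
Adam, fully seed-deterministic. SVM, random-forest, CNN-only and
LSTM-only baselines share the same interface, and 10-fold subject-level
cross-validation, ROC/AUC, t-SNE embeddings and permutation-sampling
Shapley attributions complete the evaluation.

**Simulation**: because no deposited dataset of paired sEMG/strain grip
recordings exists, `generate_cohort()` synthesizes virtual cohorts from
motor-unit first principles (fewer, larger, slower motor units in
sarcopenia; Gamma renewal firing; biphasic MUAP kernels; rate-sensitive
piezoelectric response; AWGS-consistent metadata by rejection sampling).

## Worked example

```r
library(sarcscreen)

cohort <- generate_cohort(n_subjects = 8, prevalence = 0.5, seed = 7)
cohort[, c("subject_id", "sex", "grip_kg", "smi", "chair_stand_s", "group_label")]
#>   subject_id sex      grip_kg   smi chair_stand_s group_label
#> 1 S001       female      15.0  4.64         10.8  sarcopenia
#> 2 S002       female      15.5  4.91         16.1  sarcopenia
#> 3 S003       female      16.5  4.98         12.2  sarcopenia
#> 4 S004       female      24.6  6.66          8.84 healthy
#> # ... 4 more rows

classify_awgs(cohort)[1:2, c("low_strength", "low_mass", "poor_performance", "classification")]
#>   low_strength low_mass poor_performance classification
#> 1 TRUE         TRUE     FALSE            sarcopenia
#> 2 TRUE         TRUE     TRUE             sarcopenia
```

Subject S001 is sarcopenic: grip 15.0 kg and SMI 4.64 kg/m² are both
below the female cut-offs, so low mass plus low strength classifies her
as sarcopenia even with normal chair-stand time. Her first MVC trial
shows the expected spectral signature:

```r
rec  <- cohort$recording[[1]]
wins <- segment_active_windows(rec, "br_semg")
x    <- window_samples(rec, wins[1, ])
median_frequency(x, 1000)                         # 69.7 Hz (sarcopenic band)
compute_snr(x, rec$channels$br_semg[1:2000])      # 34.3 dB

features <- mvc_normalize(extract_features(cohort))
group_compare(features)[1:4, c("feature", "mean_healthy", "mean_sarcopenia", "direction")]
#>   feature mean_healthy mean_sarcopenia direction
#> 1 rms            0.930           0.979 sarcopenia
#> 2 mav            0.897           0.952 sarcopenia
#> 3 iemg           0.179           0.190 sarcopenia
#> 4 wl             0.180           0.187 sarcopenia
```

The sarcopenic group's MVC-normalized amplitude features sit above the
healthy group's — the compensatory-activation pattern the classifier
exploits. On a full 75-subject cohort the fusion model is trained and
evaluated with

```r
dataset <- build_dataset(cohort, features, modality = "both")
cv <- kfold_cv(dataset, "cnn_lstm", k = 10, seed = 11, config = study_config())
glance(cv)          # mean_accuracy ~0.96-0.99, subject_accuracy ~0.99, auc ~0.995
autoplot(cv)        # ROC curve
```

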