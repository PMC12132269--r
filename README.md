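# graspwave

Wavelet-feature decoding of hand-grasp type from multichannel EEG.

## The problem

Brain-computer interfaces and neuroprosthetic controllers need to tell
*which* grasp a user intends — a whole-hand **power** grip, a fingertip
**precision** grip, or **no movement** — from noninvasive EEG. The
discriminative physiology is event-related modulation of sensorimotor
rhythms: alpha (~8-13 Hz) and beta (~13-30 Hz) band power over central
motor electrodes (C3/Cz/C4) changes with movement, beginning a few hundred
milliseconds after movement onset.

`graspwave` implements the complete analysis chain for epoched EEG
(trials × channels × samples at 250 Hz, 8-channel dry-electrode montage):

1. **Preprocessing** — zero-phase Butterworth band-pass (1-30 Hz),
   200 ms pre-onset baseline correction, per-channel z-scoring.
2. **Time-frequency decomposition** — complex Morlet wavelets
   $k(t) = e^{i2\pi f t} e^{-t^2/2\sigma_t^2}$ with
   $\sigma_t = n_{\text{cycles}}/(2\pi f)$, $n_{\text{cycles}} = 4$,
   centers 2/9/16/23 Hz, unit-energy normalized; power
   $= |x \ast k|^2$, with strict masking of convolution edge effects.
3. **Features** — mean, variance, skewness and excess kurtosis of the
   wavelet amplitude per channel and band over the post-onset window:
   8 channels × 4 bands × 4 statistics = **128 features per trial**,
   named `<channel>.<band>.<stat>` (e.g. `C3.alpha.kurtosis`).
4. **Classification** — RBF-kernel SVM, random forest, gradient-boosted
   trees and LDA under stratified 5-fold cross-validation (features
   standardized inside each fold), on the 3-class task and the three
   binary contrasts.
5. **Permutation feature importance** — cross-validated accuracy drops
   per shuffled feature, aggregated per band/channel and interpolated
   over the scalp (thin-plate spline, exact at electrodes).

Because no recordings ship with the package, a first-class **synthetic
EEG generator** emulates the study conditions with known ground truth:
1/f background noise plus Hann-windowed alpha/beta bursts over C3/C4 from
0.3 s post-onset, amplitude-ordered power > precision > no-movement, with
per-trial onset jitter and randomized carrier phase. Every stage is
validated against this ground truth; see
`vignettes/grasp-decoding-methods.Rmd` for the full methods account.

## Worked example

```r
library(graspwave)

cfg <- pipeline_config()                      # all analysis parameters
sim <- default_grasp_scenario(rng_seed = 7)   # 50 trials/condition, 250 Hz
epochs <- simulate_subject(sim, subject_id = "S1")
epochs <- preprocess(epochs, cfg)             # band-pass, baseline, z-score

family <- build_family(cfg, fs = 250)
tfr <- wavelet_transform(epochs, family)
feats <- extract_features(tfr, cfg$feature_window_s)
feats
#> <gw_features> subject S1: 150 instances x 128 features

run_cv(feats, task_spec("multiclass"), "random-forest", cfg)
#> <gw_cv_result> S1 / multiclass / random-forest: mean accuracy 92.7% (sd 6.4) over 5 folds

imp <- permutation_importance(feats, "random-forest", cfg)
top_k(imp, 5)
#> [1] "C3.beta_low.variance"  "C3.alpha.variance"     "C3.beta_low.mean"
#> [4] "C3.alpha.mean"         "C3.beta_high.variance"
```

The feature table has the expected 128 named columns; the random forest
decodes the three grasp conditions at ~93% (chance 33.3%) because the
generator injected class-ordered alpha/beta power at C3/C4; and the top
important features all sit at the injected channel C3 in the alpha and
beta bands — the pipeline localizes the effect it was shown. (The
`beta_high` entry is the 16 Hz burst seen by the overlapping 23 Hz
4-cycle wavelet; adjacent Morlet bins 7 Hz apart are not spectrally
disjoint.)

The full study-shaped analysis (5 subjects, all tasks and models, maps
and importance figures) is scripted in `analysis/01_simulate.R` …
`analysis/06_importance.R`; each stage reads the previous stage's outputs
under `results/`. `run_all()` performs the same end-to-end run in one
call and writes a manifest with checksums — reruns are byte-identical.

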