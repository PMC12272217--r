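# freqtag

**Frequency-tagged SSVEP simulation, RESS extraction and spatial-attention
decoding in R.**

`freqtag` is a toolbox for steady-state visually evoked potential (SSVEP)
frequency-tagging experiments on covert spatial attention — the paradigm in
which the left and right halves of a display flicker at distinct rates
(e.g. 13 and 15 Hz) so that the side a person attends to can be read out
from the EEG spectrum on single trials, even when the flicker contrast is
reduced to or below the perceptual visibility threshold. It is aimed at
cognitive neuroscientists and BCI developers who want a tested, fully
reproducible pipeline from stimulus model to decoding statistics, with a
synthetic-session generator so that every stage can be exercised and
validated without recorded data.

## What is in the box

* **Stimulus model** — amplitude-modulation-depth ↔ gray-level conversion
  (`depth_to_gray()`: depth *m* on background *g₀* gives
  ⌊g₀ + (255 − g₀)·m⌋, so 70% on gray 130 → 217), square-wave frame
  sequences on the monitor refresh grid, ideal harmonic spectra.
* **Psychophysics** — the two-phase staircase that defines *periliminal*
  (at threshold) and *subliminal* (one 0.02%-step below) modulation depths,
  with simulated logistic observers (`run_staircase()`, `observer()`).
* **Synthetic EEG sessions** — `simulate_session()` builds 32-channel,
  500 Hz recordings: occipital SSVEP sources at f and 2f with
  attention-dependent amplitude, 1/f background noise, gaze-suppressed
  alpha, event markers, and full ground truth.
* **Preprocessing** — zero-phase FIR band-pass (1651 taps, −6 dB at
  0.5/40.5 Hz), 3-SD statistical bad-channel detection, spherical-spline
  interpolation, average reference, confidence-based component pruning,
  0–9 s epoching. The chain refuses to run out of order.
* **RESS** — rhythmic entrainment source separation (`ress()`): channel
  covariances of Gaussian narrow-band (FWHM 1 Hz) filtered data at the tag
  frequency (**S**) versus its ±1 Hz neighbours (**R**) enter the
  generalized eigendecomposition **S w = λ R w**; the leading eigenvector
  is a spatial filter that maximizes SSVEP signal-to-noise ratio. SNR
  spectra and time courses use the neighbour-bin ratio
  SNR(f) = P(f) / mean P(f ± [0.5, 2] Hz), and the attention effect is
  isolated by subtracting the nontarget component (`normalize_attention()`).
* **Decoding** — per-trial RESS amplitudes over the cueing phase feed a
  linear discriminant classifier under stratified 5-fold cross-validation;
  `permutation_null()` calibrates chance with 200 label permutations and
  reports the empirical 95th/99th percentile significance boundaries.
* **IO** — BrainVision (.vhdr/.vmrk/.eeg) write/read (verified against
  MNE), TSV/JSON result files, and a one-call driver `run_pipeline()`.

## Worked example

Simulate a session, fit the two RESS filters on the high-contrast
condition, and decode the attended side with a permutation-calibrated
null:

```r
library(freqtag)

cfg  <- sim_config(n_trials_per_condition = 15, seed = 7)
sess <- simulate_session(cfg)
sess
#> <ssvep_session> 45 trials (control/periliminal/subliminal), 32 channels @ 500 Hz, 451 s

ep  <- epoch_recording(rereference_average(sess$recording))
idx <- which(ep$metadata$condition == "control")
f13 <- ress(ep, f = 13, trials = idx)
summary(f13)
#> RESS spatial filter at 13 Hz
#>   channels: 32, shrinkage: 0.01
#>   eigenvalues (top 5): 66.97, 2.075, 1.943, 1.786, 1.721
#>   strongest topography channels: O2, PO10, Oz
f15 <- ress(ep, f = 15, trials = idx)

feats <- extract_features(subset_epochs(ep, idx), f13, f15)
permutation_null(feats, n_perm = 200, seed = 1)
#> <ssvep_decode> 15 trials, 5-fold stratified CV: 95.0%
#>   permutation null (200): mean 50.6%, boundaries 95th = 76.7%, 99th = 90.0%
#>   significant: p<.05 TRUE, p<.01 TRUE
```

Reading the output: the top generalized eigenvalue (λ ≈ 67) says the RESS
component carries ~67× more narrow-band power at 13 Hz than its spectral
neighbourhood, with the occipital topography (O2/PO10/Oz) expected for a
visual response; decoding the attended hemifield from 15 high-contrast
trials reaches 95% accuracy, above the 95th (76.7%) and 99th (90.0%)
percentiles of its own 200-permutation null, so the attention readout is
significant at α = .01. Note how far the small-sample chance boundaries
sit above the theoretical 50%.

`run_pipeline(sim_config(seed = 1), out_dir = "out")` performs the whole
chain (simulate → preprocess → RESS → decode) and writes the BrainVision
recording, ground truth, filters, decoding table and a JSON report.

## Vignette

`vignettes/freqtag-methods.Rmd` documents the generative model behind the
simulator, every tunable parameter with units and defaults, the numerical
choices (filter design, covariance shrinkage, eigenvector sign and
percentile conventions), and what the synthetic benchmark does and does
not establish about recorded EEG.
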