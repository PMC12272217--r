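---
title: "Models and methods behind freqtag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind freqtag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the generative model
behind the synthetic sessions, the signal-processing and statistical
choices in each stage, the parameters that matter, and the limits of what
the synthetic benchmark can establish.

## 1. The paradigm being modelled

In a frequency-tagged spatial-attention task, the left and right regions of
a display flicker at distinct rates (here 13 Hz left, 15 Hz right) while a
participant fixates centrally (3 s), is cued to covertly or overtly attend
one side (3 s), and then responds to a target there (3 s). The flicker
drives a steady-state visually evoked potential (SSVEP) — an occipital EEG
oscillation at the stimulation frequency and its harmonics — whose
amplitude grows when the tagged region is attended. Because the two sides
carry different tags, the attended side can be decoded from the relative
13/15 Hz response on a single trial.

The interesting regime is low stimulus contrast. The flicker's *amplitude
modulation depth* is the fraction of the background-to-white gray range
spanned by its two states: the ON gray level is `floor(g0 + (255 - g0) *
m)` on background `g0 = 130`, so the 70% "control" flicker alternates
between 130 and 217. A two-phase staircase finds each observer's perceptual
visibility threshold: blocks of four 1-s stimuli (the two flickers plus two
static catch stimuli) descend from 5% of maximal depth in 0.1-point steps
until a block has more than two errors, then ascend in 0.02-point steps
until both flickers in a block are detected. The final ascending depth is
the *periliminal* depth; one ascending step below it is *subliminal*.

## 2. The synthetic session generator

`simulate_session()` produces the statistical structure this analysis
assumes, plus ground truth, so that every downstream stage is testable
without recordings. Channels follow a 32-electrode 10–20 montage with
unit-sphere positions; per channel the signal is a sum of:

* **Two SSVEP sources**, one per tag frequency, modelled as sinusoids at
  f and 2f (relative weights 1 and 0.3). The analysis only characterizes
  f and 2f, so a full square-wave following response would add nothing
  testable. Each source projects to the scalp through a Gaussian
  parieto-occipital topography centred contralaterally to its stimulus.
* **1/f background noise**, independent per channel, synthesized in the
  frequency domain (`make_pink_noise()`), default slope 1 and RMS 2.5 µV.
* **A posterior alpha rhythm** (8–12 Hz narrow-band noise, 1.5 µV RMS)
  multiplied by 0.7 during the cue and target phases — the suppression
  that accompanies the gaze/attention shift at cue onset.

Source amplitude on a trial with modulation depth *m* is
`ssvep_gain * contrast_response(m)` with `contrast_response(m) = m^gamma`
(γ = 0.5 by default; no published functional form constrains it, so it is
a configurable power law through (0,0) and (1,1)). From cue onset the
attended side's amplitude rises linearly over 0.5 s — attentional
modulation takes effect in about half a second — to `attention_ratio`
(default 1.5) times baseline, and stays there through the target phase.

Two generator choices deserve explanation:

* **Attention requires visibility.** Covert attention cannot be deployed
  to a flicker the observer cannot see, so the attentional gain applies
  only at depths at or above `visibility_threshold` (default 0.02, the
  periliminal depth). This is what makes the subliminal condition decode
  near chance although its depth differs from periliminal by only 0.0002:
  the stimulus energy is almost identical, but the attentional asymmetry
  that the decoder exploits is absent.
* **Trial-to-trial amplitude variability.** Each source's amplitude is
  multiplied per trial by a unit-mean log-normal factor
  (`amplitude_jitter = 0.12` on the log scale). Real SSVEP amplitudes
  fluctuate with arousal and attentional state, and without this term
  single-trial decoding of the high-contrast condition saturates at 100%
  no matter the sensor noise — spatial filtering over 32 channels
  suppresses additive noise too well. The jitter is what keeps the
  control condition *near*, not *at*, ceiling.

With the frozen defaults (`ssvep_gain = 1.5` µV, `noise_rms = 2.5` µV,
`amplitude_jitter = 0.12`), 90-trial sessions decode at roughly 95–100%
(control), 70–80% (periliminal) and chance (subliminal) — the qualitative
profile the pipeline is meant to reproduce; the exact values are computed
by the test suite, not asserted here.

## 3. Preprocessing

The conditioning chain is fixed — band-pass → bad channels → interpolation
→ average reference → optional component pruning → epoching — and each
step records itself in the recording's history so a reordering raises an
error rather than silently changing the result.

* **Band-pass.** A linear-phase Hamming windowed-sinc FIR, 1651 taps at
  500 Hz (rescaled proportionally at other rates), passband 1–40 Hz,
  applied once with group-delay compensation. The taps are the textbook
  difference of two windowed sincs because that construction places the
  half-amplitude (−6 dB) points exactly at the 0.5 and 40.5 Hz cutoffs
  (measured −6.04 dB); `signal::fir1`'s scaling puts them at −4.3/−8.1 dB,
  which is why the kernel is authored in-package.
* **Bad channels.** A channel is flagged when the mean log₁₀ Welch PSD
  over 1–40 Hz (2 s segments, 50% overlap) deviates from the
  cross-channel median by more than 3 robust SDs (1.4826·MAD). The log
  and the robust scale make the rule insensitive to a single broken
  channel inflating the spread.
* **Interpolation.** Perrin-style spherical splines (order m = 4, 7-term
  Legendre truncation, ridge 1e-5) rebuilt from the good channels; these
  are the conventional defaults, and no installed package provides the
  primitive. Interpolations are counted because each one reduces the
  effective data rank.
* **Average reference** subtracts the instantaneous channel mean (rank
  −1, recorded via `effective_rank()`).
* **Component pruning** owns only the decision rule: given any linear
  decomposition (e.g. ICA from an established implementation) and
  per-component classification confidences, components exceeding 0.70
  confidence — strictly — for any artifact class (ocular, muscular,
  heart, line, electrode, other) are removed. The decomposition itself is
  deliberately an input: simulated sessions contain no stereotyped
  artifacts, so the synthetic pipeline skips this stage by default.
* **Epoching** cuts [0, 9] s windows with fixation onset at 0 (fixation
  0–3 s, cue 3–6 s, target 6–9 s); trials overrunning the recording are
  dropped with a warning and counted.

## 4. RESS

Rhythmic entrainment source separation contrasts the channel covariance
**S** of data Gaussian-filtered at the tag frequency (FWHM 1 Hz) with the
mean covariance **R** at the two ±1 Hz neighbours (same FWHM), both
averaged over trials on the window 0–6 s after cue onset (the cue and
target phases). Solving **S w = λ R̃ w** and keeping the eigenvector with
the largest eigenvalue yields a spatial filter maximizing narrow-band SNR;
applied to the epochs it gives one component time series per trial.

Numerical choices:

* **Shrinkage.** R̃ = (1−s)·R + s·mean(eig(R))·I with s = 0.01.
  Average-referenced (rank-deficient) data makes R singular; 1% of the
  mean eigenvalue is enough to stabilize the Cholesky-whitened
  symmetric eigenproblem without visibly biasing the filter.
* **Sign convention.** An eigenvector's sign is arbitrary; it is fixed so
  the component topography (S w) is positive at the posterior midline
  channel, giving reproducible traces.
* **Degeneracy.** If the eigenvalue spectrum is flat (S ∝ R̃) the fit is
  flagged: no direction is preferred and the "component" is noise.
* **SNR definition.** No single formula is canonical; the package uses
  the neighbour-bin ratio SNR(f) = P(f) / mean P over bins 0.5–2 Hz away
  on both sides (both configurable). Featureless noise then has
  expectation ≈ 1 at every frequency, which the tests verify.
* **Time-resolved SNR** slides a 2 s window in 0.1 s steps (window-centre
  timestamps). Two seconds is the shortest window resolving a 1 Hz FWHM
  structure; the cost is temporal smearing of ±1 s, so onset latencies
  read from these traces are quantized upward.
* **Attention normalization.** The RESS filter overfits its own
  frequency, so the attentional effect is referenced against the
  nontarget filter. Two conventions exist in the field's reporting and
  both are implemented: `mode = "signal"` (default) subtracts the
  nontarget component *time series* from the target component before
  computing SNR; `mode = "snr"` subtracts the two components' SNR
  *traces* (each at its own frequency). They answer slightly different
  questions and neither is guessed to be "the" right one; the default
  follows the subtraction-in-signal-space description, the alternative
  matches target-minus-nontarget SNR plots.
* **Per-condition fitting.** Filters are fitted separately per condition
  and per frequency (six per session), pooling left- and right-cue
  trials of that condition; pooling keeps the filter common to the two
  classes the decoder must separate, avoiding label leakage through the
  spatial weights.

## 5. Decoding and statistics

Features are the RMS amplitudes of the two narrow-band (FWHM 1 Hz) RESS
components over the 3 s cueing phase — the window in which attention
shifts but before target-evoked activity. A two-class linear discriminant
with pooled within-class covariance is scored by stratified 5-fold
cross-validation (folds seeded; accuracy is the mean over folds, in %).
The discriminant is the closed-form rule, implemented in-package and
cross-checked for exact prediction agreement with `MASS::lda`; the
closed form matters because the permutation machinery refits it roughly
10⁵–10⁶ times in the validation suites.

Small samples make the theoretical 50% chance level misleading, so
significance is calibrated per dataset: 200 random label permutations
(class counts preserved, folds re-drawn each time) build an empirical null,
whose 95th and 99th percentiles (linear-interpolation convention) are the
α = .05 and .01 boundaries. The observed accuracy must exceed a boundary
*strictly*; ties are non-significant, which together with the discreteness
of 30-trial accuracies makes the test slightly conservative (the measured
type-I rate in the suite is ~3.6% at nominal 5%). For 30-trial two-feature
null datasets the pooled boundaries fall near 68% and 72%.

The baseline/response threshold displayed over SSVEP time courses is the
root-node split of a depth-2, ≤2-feature decision tree (rpart, cp = 0)
separating fixation-phase from cue/target-phase single-trial SNR; a
held-out accuracy check flags the threshold as uninformative when the
phases are in fact inseparable.

## 6. The staircase simulator

Observers are logistic:
P(detect) = guess + (1 − guess − lapse) / (1 + exp(−β(depth − t))), with
false-alarm probability `guess` on static stimuli. The error rule counts
both flicker misses and static false alarms toward the "more than two
errors" descending trigger — in a four-trial block with only two flicker
trials, the trigger is unreachable otherwise. The printed protocol is
ambiguous on this point; the package documents the choice rather than
hiding it. A consequence worth knowing: an observer who never false-alarms
descends to depth 0 without triggering (this raises a protocol-failure
flag), and the ascending phase then does all the work — which it does
correctly, since below threshold such an observer never stops the ascent
early. The default `guess_rate = 0.1` reflects that near-threshold
detection blocks elicit frequent false alarms. Steps are absolute
percentage points of maximal depth (5% → 4.9% → …), each depth stays on
the lattice {0.05 − 0.001·i + 0.0002·j}, and the descending trigger is
evaluated only on completed blocks.

## 7. Problem sizes in the validation suite

The suite exercises the pipeline at sizes chosen to make the statistical
checks meaningful while remaining a routine desk run: 200 null datasets ×
200 permutations for the chance-boundary calibration, 500 datasets for the
type-I rate, 500 simulated observers for staircase recovery, 20 random
mixtures for GED optimality, ten 90-trial sessions for the
condition-ordering check and a 4-point attention-ratio ladder with ten
30-trial sessions per rung. Fixture sessions elsewhere use 10–30 trials.

## 8. What passing tests do and do not show

The generator reproduces the *statistical skeleton* of a frequency-tagging
session: narrow-band sources with attention- and contrast-dependent
amplitude, 1/f noise, suppressible alpha, realistic trial counts. It does
not simulate ocular or muscular artifacts (hence no ICA in the synthetic
path), volume conduction through a head model, inter-subject topography
variability, line noise, or non-stationary drifts. Passing the suite
therefore shows the *algorithms* are correct and the pipeline is sensitive
under honest noise — not that any particular accuracy level will be
attained on recorded EEG. Likewise the contrast-response exponent and the
visibility-attention coupling are modelling choices constrained only by
qualitative orderings; absolute per-condition amplitudes in microvolts are
not calibrated to any dataset. EDF input is not supported (BrainVision
only), and the RESS implementation extracts a single component per
frequency rather than a denoising subspace.
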