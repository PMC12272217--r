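Package: freqtag
Title: Frequency-Tagged SSVEP Simulation, RESS Extraction and Spatial-Attention Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for steady-state visually evoked potential (SSVEP)
    frequency-tagging experiments on spatial attention. Simulates multichannel
    EEG sessions with flicker-locked sources, 1/f background noise and
    gaze-contingent alpha activity; models flicker stimuli (modulation-depth to
    gray-level conversion, frame-grid square waves) and the two-phase
    psychophysical staircase that defines periliminal and subliminal contrast
    levels; preprocesses continuous recordings (zero-phase FIR band-pass,
    statistical bad-channel detection, spherical-spline interpolation, average
    reference, component pruning, epoching); extracts SSVEP components by
    rhythmic entrainment source separation (RESS), a spatial filter obtained
    from the generalized eigendecomposition of target-band versus
    neighbour-band covariance matrices, with target-minus-nontarget attention
    normalization; and decodes the attended hemifield on single trials with a
    linear discriminant classifier, stratified cross-validation and
    permutation-calibrated chance boundaries. Recordings round-trip through the
    BrainVision format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    rpart,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
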