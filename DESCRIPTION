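Package: fogmm
Title: Multi-Modal Detection of Freezing of Gait from Wearable Sensor Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based detection of Freezing of Gait (FOG) episodes in
    Parkinson's disease from multi-modal wearable recordings: tri-axial
    inertial sensors at the tibia and wrist, multi-electrode EEG and skin
    conductance. Provides a synthetic cohort generator with ground-truth
    episode annotations, per-modality preprocessing (z-score
    standardization, Butterworth and Chebyshev band-pass filtering, bipolar
    EEG montage, phasic/tonic skin-conductance decomposition, resampling to
    a common 500 Hz rate), overlapping-window segmentation and labeling, a
    large time- and frequency-domain feature battery including the freeze
    index and magnitude-squared coherence, correlation-based feature
    selection with redundancy pruning, subject-independent (nested
    leave-one-subject-out) and subject-dependent (10-fold CV +
    leave-one-task-out) SVM/kNN classification, majority-vote smoothing and
    window- plus episode-level evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
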