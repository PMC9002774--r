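---
title: "Multi-modal freezing-of-gait detection: models, parameters and design choices"
author: "fogmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal freezing-of-gait detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogmm)
```

## The problem

Freezing of Gait (FOG) is an episodic inability to progress forward while
walking, characteristic of advanced Parkinson's disease. Episodes are
sporadic, often short (many last under 10 s), and hard to observe during
clinic visits, which motivates automatic detection from body-worn sensors.
`fogmm` implements a window-based detector over four modalities — tri-axial
accelerometer and gyroscope at the lateral tibia and at the wrist,
multi-electrode EEG, and skin conductance (SC) — together with a synthetic
cohort generator so that the entire pipeline is testable end to end without
any data download.

The physiological signature the detector exploits is spectral: during normal
walking the shank acceleration spectrum concentrates in the *locomotion
band* (0.5–3 Hz); during trembling-in-place freezing it shifts into the
*freeze band* (3–8 Hz) while movement amplitude drops. The *freeze index* —
the ratio of freeze-band to locomotion-band power — and its bounded
companion, the *freeze ratio* P(3–8)/P(0.5–8), quantify this shift per
window. (The freeze ratio is not given a formula in the source literature we
follow; the bounded variant is this package's documented choice, stated in
every output that reports it.)

## Pipeline overview

1. **Simulation** (`simulate_cohort`) — multi-modal recordings with
   ground-truth episode annotations.
2. **Preprocessing** (`preprocess_recording`) — per-modality conditioning,
   common 500 Hz rate.
3. **Windowing** (`segment_windows`) — 3 s windows, 90% overlap, majority
   labeling.
4. **Features** (`extract_features`) — 186 tibial + 168 wrist + 1107 EEG +
   39 SC columns.
5. **Selection** (`select_features`) — correlation filter plus redundancy
   pruning.
6. **Classification** (`fog_sia`, `fog_sda`) — SVM/kNN over a hyperparameter
   grid, nested leave-one-subject-out (subject-independent) or 10-fold CV +
   leave-one-task-out (subject-dependent).
7. **Evaluation** (`evaluate_fit`) — window metrics, 5-window majority-vote
   smoothing, episode-level detection tally.

`run_pipeline(fog_config(...))` executes the chain and can persist every
intermediate artifact.

## The synthetic cohort generator

The generator is first-class, tested code: its defaults define the study
conditions used by the package's own validation.

**Movement.** Walking is a cadence sinusoid (per-subject frequency drawn
once from 1–2.5 Hz) plus two decaying harmonics (amplitude ratios 1 : 0.3 :
0.15) and Gaussian noise (sd 0.1); freezing replaces it with a single
trembling sinusoid at a per-subject 4–7 Hz frequency, scaled by
`fog_amplitude_ratio` (default 0.5). On long clean segments at least 70% of
the 0.5–16 Hz power lies in the regime's own band. Wrist behaviour is
deliberately heterogeneous: per subject a coin decides between arm-swing
attenuation and freeze-band trembling during episodes, reflecting how
variable upper-limb involvement is across patients.

**Episodes.** Counts per task are Poisson (`fog_rate`, default 2/min);
durations are log-normal with median 8 s and log-sd 1.1, truncated to
1–200 s, so roughly a third of episodes are shorter than 5 s and about half
shorter than 10 s — the clinically reported pattern. Episodes are placed
uniformly in the free time of the task with a refractory gap of at least 2 s
between consecutive episodes; draws that cannot fit are resolved by
dropping the longest episodes (rare at the default rate).

**EEG.** 28 raw electrode channels at 1000 Hz: pink (1/f) background plus
band-limited oscillators placed at physiologically motivated sites (theta at
fronto-central electrodes, alpha occipito-parietal, beta central-parietal).
Inside episodes each oscillator's power is multiplied by
`eeg_fog_band_shift` (default: theta ×2, beta ×1.5, alpha ×0.7), emulating
the band-power shifts reported for the fronto-central cortex during FOG.

**SC.** A slow tonic drift plus anticipatory phasic bumps that begin within
2 s *before* each episode onset (exponential rise/decay, gain 0.3 µS); the
sensor-level signal is returned as galvanic resistance, the reciprocal of
conductance, as delivered by real hardware. The timing of the bumps is a
modeling choice — the literature reports pre-FOG sympathetic changes without
quantitative morphology.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: biomechanically realistic gait (no
stride-to-stride variability, no turning dynamics), graded freeze severity
(regimes are binary, so class separation is stronger than clinical data),
EEG artifacts (ocular/muscle contamination is out of scope), and sensor
nonidealities (drift, saturation). End-to-end accuracy on this cohort is a
*parameter-recovery* check of the pipeline, not a clinical performance
claim.

## Preprocessing choices

* **Standardization.** Each inertial and EEG channel is z-scored with the
  population (1/n) standard deviation before filtering, removing
  inter-subject amplitude scale. SC is *not* z-scored: its features rely on
  physical phasic/tonic morphology (e.g. the tonic slope in µS/s), which
  standardization would destroy.
* **Filters.** Inertial: 4th-order Butterworth high-pass at 0.5 Hz +
  5th-order low-pass at 16 Hz. EEG: 5th-order Chebyshev-I high-pass at
  1.6 Hz + 6th-order low-pass at 30 Hz after re-referencing to an 18-channel
  longitudinal bipolar montage. All filters are applied zero-phase
  (forward–backward) because the analysis is offline and window labels must
  not be shifted against the annotations; zero-phase application squares the
  magnitude response, so the Chebyshev passband ripple is set to 0.25 dB per
  pass (~0.5 dB effective). Edge transients are absorbed by odd-reflection
  padding (10 s for the 0.5 Hz high-passes, whose step response decays with
  a ~0.8 s time constant).
* **Montage.** The electrode set does not admit the classical double-banana
  exactly, so the default 18 derivations are four anterior-to-posterior
  chains (two temporal, two parasagittal) over the available electrodes; the
  montage is a configurable input and is recorded with every run.
* **Order of operations.** standardize → filter at the native rate →
  resample to 500 Hz (polyphase band-limited; the native rates 100 and
  1000 Hz are exact rational ratios of 500). Filtering at the native rate
  keeps interpolation artifacts out of the band-power features. SC instead
  is converted to conductance, resampled, then decomposed at 500 Hz — the
  decomposition is linear, so the phasic/tonic additivity SCR + SCL =
  SC_filtered holds exactly either way.
* **SC transients.** The source procedure asks for suppression of rapid
  artifact transients without defining detection. We flag samples whose
  absolute first difference exceeds 5× its median-absolute-deviation scale
  for runs shorter than 0.5 s, dilate flagged spans by 0.25 s, and replace
  them with a centered 4 s moving average (3–6 s is sensible; 4 s is the
  default).

## Windowing and labeling

3 s windows every 0.3 s (90% overlap), anchored at t = 0 of each task.
A window is FOG when *strictly more than half* of its samples fall inside an
annotated episode; the exact-half tie goes to nonFOG (conservative toward
the negative class, and "largest number of samples" implies a strict
majority). Episodes are half-open intervals [start, end), so a sample is
never counted twice at a boundary. Episodes shorter than 3 s are excluded
before labeling — they are below the detector's effective time resolution
(about 4 s after 5-window majority voting). Windows straddling an excluded
episode are simply labeled by the majority rule against the filtered
annotation set.

## The feature registry

Column totals per sensor are a hard contract (186 / 168 / 1107 / 39),
checked by the test suite on every extraction. Where the printed feature
lists in the source material are ambiguous or internally inconsistent, the
registry is calibrated to those totals and every column is documented by
`feature_dictionary()`:

* **Tibia** (6 channels × 31): 17 frequency features per axis (spectral
  moments and shape, locomotion/freeze band powers and their within-band
  PSD spread, freeze index, freeze ratio) + 14 time features (the 14th is
  the Pearson correlation with the companion axis: x·y, y·z, z·x).
* **Wrist** (168): per component 7 frequency + 13 time features; the
  accelerometer magnitude additionally carries sixteen 1 Hz band powers,
  locomotion/freeze band powers and the 9–12 / 13–16 Hz powers (33 columns
  with the 3 pairwise axis correlations), the gyroscope magnitude the
  reduced 15-column set.
* **EEG** (1107): 16 frequency + 3 time features per bipolar channel
  (19 × 18 = 342; Max Power is the 16th frequency feature, added so the
  enumeration meets the published total), plus magnitude-squared coherence
  averaged in the five bands delta 1.6–4, theta 4–8, alpha 8–13, beta1
  13–20, beta2 20–30 Hz for all 153 channel pairs (765). The band edges are
  bounded by the 1.6–30 Hz filter band.
* **SC** (39): phasic 10 frequency + 9 time; first and second central-
  difference derivatives of the phasic component, 8 time features each;
  tonic 3 frequency features + least-squares slope.

**Spectral estimation.** All "power" features derive from a Welch estimate:
1 s Hann segments with 50% overlap (five segments per 3 s window; 1 Hz
resolution). Band powers integrate the PSD trapezoidally with interpolated
band edges. Note a resolution effect worth knowing: a tone at 1 Hz loses
part of its leakage below the 0.5 Hz band edge at 1 Hz resolution, so
band-power equality checks in the tests use longer segments where exact
ratios matter. Peak detection uses local maxima with prominence at least
0.1 of the window standard deviation. Windows with no detected peaks report
0 for peak-derived features; an all-zero spectrum reports 0 for the moment
features — both rules keep the matrix free of non-finite values. The freeze
index of a window with zero locomotion-band power is +Inf by definition;
range normalization clips such sentinels to the feature's upper bound.

**Range normalization.** Min–max scaling onto [0, 1] with statistics fitted
on training rows only; held-out rows are transformed with the training
min/max and clipped. Fitting on all rows would leak held-out information
into the cross-validation. Constant training columns are dropped with a
warning.

## Feature selection

Features are retained when their Pearson correlation with the 0/1 label
satisfies |r| ≥ 0.35 (subject-independent) or ≥ 0.4 (subject-dependent) with
p < 0.05 from the exact t-transform on n − 2 degrees of freedom; overlapping
windows are treated as independent here, as the source analysis implicitly
does. The absolute value matters: features that *decrease* during freezing
(locomotion band power, RMS) are retained with negative r. Redundant
survivors (|pairwise r| ≥ 0.86) are pruned greedily in descending |r| with
name-based tie-breaking, each survivor claiming its redundant partners.

Pruning operates **within each sensor's feature set** by default: the
analysis keeps a separate feature set per sensor through normalization and
selection, and cross-sensor claims would otherwise let a single strong
feature (e.g. a gyroscope freeze ratio) erase the complementary sign
structure of another sensor (e.g. accelerometer locomotion-band power,
which carries negative label correlation). `groups = "none"` restores
global pruning. In the subject-independent procedure, selection is fitted
inside each outer training fold — never on the held-out subject; a flag
(`correlation_select` on the pooled data) reproduces the all-data variant
when the cohort-level table itself is of interest.

## Classifiers and cross-validation

Two families: SVM (linear, quadratic, cubic, gaussian kernels; kernel scale
and cost in [0.1, 100]) and kNN (1–180 neighbours; cityblock, euclidean,
squared-euclidean metrics; equal, inverse, squared-inverse distance
weights). The squared-euclidean metric is a monotone transform of euclidean
and always ranks neighbours identically — it matters only through the
distance weights. Hard decisions only; ties in the neighbour vote go to
nonFOG.

`fog_grid("full")` samples the continuous ranges at 5 log-spaced points
(154 cells) — the documented reference grid. The default for the synthetic
study is `fog_grid("compact")`, 4 cells spanning both families; on the
generator's well-separated regimes the inner selection is insensitive to
the grid density, and the compact preset keeps a full nested
leave-one-subject-out run on 6,000+ windows in the low minutes on one core.
Both presets are plain data frames and can be replaced by any custom grid.

**Subject-independent (SIA).** For each of N outer folds, one subject is
held out; selection and normalization are fitted on the N−1 training
subjects; an inner leave-one-subject-out loop over those N−1 subjects scores
every cell by mean inner F-score (the aggregation the inner "best
performance" maximizes is configurable in principle; mean F across inner
folds is the default because F is the study's primary metric). The best SVM
cell and best kNN cell then compete under the model-choice rule: the family
maximizing *both* accuracy and F wins; if they disagree, F decides; exact
ties break lexicographically. The winner is refit on all N−1 subjects and
applied to the held-out subject. Training subjects lacking both classes are
excluded from inner validation with a warning (mirroring cohorts where a
patient contributes no freezing). Per-fold choices may differ; the modal
configuration is refit on all data as the "consensus" model that
`predict()` uses, and is reported alongside the per-fold table.

**Subject-dependent (SDA).** Per subject: leave-one-task-out on the outside,
stratified 10-fold cross-validation on the training tasks' windows for
hyperparameter choice (stratification keeps both classes in every fold
whenever feasible; fold assignment is seeded and reproducible). Subjects
with FOG windows in fewer than two tasks are rejected — with only one
freezing task, a task-held-out test set would have no positive class.

A leakage audit (`leakage_audit`) verifies per fold that no test row index
entered any fitting step, and a label-permutation control in the test suite
checks that shuffled labels yield chance-level accuracy — the standard
guards against contaminated cross-validation.

## Evaluation

Window-level: TP/FP/FN/TN and sensitivity, specificity, precision,
accuracy, F-score. Metrics with empty denominators are reported as `NA`,
never as 0 — coercing them would silently inflate averages. Majority-vote
smoothing replaces each prediction with the majority of its centered
5-window neighbourhood (~4 s at the 0.3 s hop); stream edges use the
available shorter neighbourhood rather than discarding the first and last
windows. Episode-level: an annotated episode (≥ 3 s, post-exclusion) counts
as detected when at least one post-smoothing FOG window overlaps it — the
weakest defensible criterion given the ~4 s time resolution; the minimum
overlap is configurable. Whether detection should use raw or smoothed
predictions is not fixed by the source description; smoothed is the default
since majority voting is described as part of both algorithms.

## Problem sizes used in the packaged studies

The package's own end-to-end study (test suite and `scripts/acceptance.R`)
uses 8 subjects × 2 tasks × 120 s with tibial sensors only (≈ 6,300
windows × 186 features), the compact grid, and a single-subject 4-task × 90 s
subject-dependent run. These sizes exercise every stage — including episode
statistics stable enough for detection-rate estimates — while a full run
stays in the minutes range on a single core. Larger cohorts scale linearly
in subjects and quadratically in nothing.

## Known limitations

* The generator's binary walking/freezing regimes make class separation
  easier than clinical recordings; reported synthetic metrics are upper
  bounds of a sanity check, not clinical estimates.
* A side effect of the binary regimes: the freeze ratio and the
  locomotion-band power are near-deterministic functions of the same
  spectral-mass shift and end up cross-correlated around −0.9 on synthetic
  windows, above the 0.86 redundancy threshold — so pruning keeps only the
  stronger of the two (the freeze ratio). On clinical data, where severity
  is graded and walking intensity varies, both survive selection with
  opposite signs. Sign-structure checks on the pruned synthetic selection
  therefore see only the freeze-type features; the complementary negative
  correlation of locomotion-band power is visible at the correlation-filter
  stage (`correlation_select`) of every fold.
* EEG artifact removal is out of scope; the EEG path assumes artifact-free
  (synthetic) input.
* Overlapping windows are correlated, but selection p-values treat them as
  independent — a deliberate fidelity to the source analysis rather than a
  statistical recommendation.
* The exact 18 bipolar derivations are a documented default, not a ground
  truth; results should always be reported together with the montage used.
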