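---
title: "Methods: raw-EEG emotion classification with eegemotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: raw-EEG emotion classification with eegemotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modeling idea

Scalp EEG carries valence-related information, concentrated over frontal and
temporal sites, but its feature distributions drift between people, sessions
and recording setups. Classifiers trained on spectral band-power features of
one group of subjects often degrade sharply on a new subject. `eegemotion`
implements the raw-signal alternative: no hand-crafted features are extracted
at all. Windows of raw, amplitude-normalized EEG are handed to a
convolutional backbone whose pooled activations feed a dense classification
head, and the only post-processing is a temporal median filter on the
predicted label sequence. The package's purpose is to make every stage of
that pipeline reproducible, testable and auditable at desk scale.

The working assumptions are:

* trial labels (negative / neutral / positive valence) apply uniformly to
  every window cut from the trial;
* the emotional state is approximately constant over a span of a few
  seconds, which justifies median-filtering consecutive window predictions;
* recordings arrive band-limited (the public emotion-EEG datasets are
  distributed pre-filtered), so in-package filtering is optional.

## Pipeline stages and their parameters

**Windowing** (`make_windows`). Trials are cut into windows of `N` samples
(default 300) at stride `N − N/6`; consecutive windows share `N/6` samples
(50 for the default). `N` must be at least 75 — the backbone's minimum input
width — and divisible by 6 so that the overlap is an integer number of
samples; windows are anchored at multiples of the stride and trailing
samples shorter than a window are discarded rather than padded. A window is
`N / fs` seconds long: 1.5 s at 200 Hz, about 2.3 s at 128 Hz, 0.6 s at
500 Hz. Keeping `N` fixed in samples across sampling rates (rather than
resampling) is a deliberate property of the approach.

**Channel selection** (`select_channels`). The default montage is the nine
frontal/temporal electrodes in the fixed window arrangement AF1, AF2, F3,
F4, F5, F6, F7, T7, T8 — four left/right asymmetric pairs plus F7, chosen
because valence expression in EEG is strongest frontally and asymmetrically.
(Electrode naming conventions differ across caps; F5/F6 on some montages are
labeled F7/F8 on others. The arrangement string above is normative for this
package; `select_channels` takes any explicit list.)

**Tensorization** (`assemble_tensor`). A window of `S` channels must fill a
backbone input of `N1 ≥ 75` rows (default 80). Each channel row is followed
by `NNC = ceil(N1/S) − 1` noisy copies — the row plus i.i.d. Gaussian noise
with mean 0 and standard deviation `sigma = 0.01` — and the stacked
`S·(NNC+1)` rows are truncated to the first `N1`. The stack order is a
configuration choice (`layout`): the default `"channel_blocks"` keeps each
original immediately followed by its copies, so originals sit at rows
`m·(NNC+1)`; the alternative `"originals_first"` puts all originals at the
top. For the default 9 channels into 80 rows, `NNC = 8`, the 81st row (one
copy of the last channel) is dropped, and all 9 originals survive — the
sufficient condition `(S−1)(NNC+1) ≤ N1−1` is asserted in the test suite.
The construction is repeated with independent noise draws for each of
`depth = 3` slices; original rows are bit-identical across slices. `sigma`
is expressed in the amplitude units of the data. Because raw EEG amplitudes
(tens of microvolts) dwarf an absolute 0.01, the copies are near-duplicates
of their channel — which is the intent: augmentation that preserves channel
content while breaking exact duplication. For experiments that want noise
proportional to signal scale, `sigma_scale_rows = TRUE` rescales `sigma` by
each row's standard deviation.

**Normalization** (`normalize_tensor`). Each row of each slice has its mean
removed, independently, originals and copies alike, so every row is
zero-mean within its window. This removes electrode offset and slow drift
(and, incidentally, the simulator's additive per-subject offset) and
protects training from ill-conditioned inputs. It is idempotent and is
applied after augmentation, matching the stage order windowing →
reshaping/augmentation → normalization.

**Classifier** (`build_model`, `train_model`). The model is backbone →
global average pooling → dense head. The head defaults to widths
1024, 1024, 1024, 512 with ReLU, then a softmax layer of width `z` (2 or 3
classes); an empty width vector gives the ablated pooling-plus-softmax
model, which is how the contribution of the dense stack can be measured.
Training minimizes categorical cross-entropy with an L2 penalty on dense
weights (coefficient `1e-4` by default; the penalty strength and learning
rate are configuration, since only the regularizer family and optimizer are
fixed by the recipe) using Adam (learning rate `1e-3`), minibatches of 64
with reshuffling each epoch, at most 100 epochs. A stratified random
fraction (`val_fraction = 0.2`) of the *training subjects'* windows forms
the validation set; training stops early when the best validation accuracy
has not improved for 6 consecutive epochs, and the weights of the
best-validation epoch are restored. "Improved" means strictly greater at a
`1e-6` tolerance. Probability ties at prediction resolve to the lowest
class code.

**Backbones.** The built-in `SURROGATE_SMALL_CNN` is a fixed,
He-initialized, seeded random-weight CNN: four blocks of 3×3 valid
convolution, ReLU and 2×2 average pooling (filter counts 8, 16, 32, 32),
followed by global average pooling. Rectified random convolutional features
behave as band- and scale-selective energy detectors and are a recognized
untrained-feature baseline; the package trains only the dense head on top of
them. This backbone is deliberately frozen: the design is feature extraction
plus head training, with the backbone seed part of the configuration.
`INCEPTION_RESNET_V2` names the full-fidelity mode with the same (75, 75)
minimum-input contract; its weights are not shipped, so it delegates to a
user-supplied `features_fn` (e.g. an exported pretrained network) and
otherwise fails with an explicit message. Results obtained with the
surrogate characterize the pipeline, not the representational power of a
large pretrained backbone.

**Output median filter** (`median_filter_labels`). Classes are ordered on
the ordinal valence axis −1 < 0 < +1 (negative, neutral, positive); each
predicted label is replaced by the median ordinal in a centered window of
`size = 5` predictions. The valence ordering is what makes a categorical
median meaningful with three classes; with two classes the filter reduces
exactly to a sliding majority vote (property-tested against an independent
majority-vote oracle). With the default stride of 250 samples at 200 Hz,
five windows span (5−1)·1.25 s + 1.5 s = 6.5 s — the interval over which
the emotional state is assumed stable. Edge handling defaults to `SHRINK`
(recompute over the truncated window); truncated edge windows can have even
length, in which case the *lower* median is taken so the output is always a
label present in the window. Filtering is applied per contiguous trial
within a subject's sequence (never across subjects; `span_trials = TRUE`
merges a session's trials when the deployment scenario is one continuous
stream).

## Evaluation protocols

`run_loso` holds out one subject at a time: the held-out subject's windows
appear in neither the training nor the validation split, and the report's
audit trail records the subject sets used in every role of every fold so the
no-leakage property is checkable after the fact. Accuracy is the percentage
of correctly labeled windows, reported per subject with mean and standard
deviation, before and after filtering. Because the surrogate backbone is
fixed and untrained, its features are computed once per cohort and reused
across folds — a cache with no information flow from test to train.

`run_cross_dataset` trains once on all subjects of one cohort and evaluates
each subject of another, after reducing both to the positive/negative scheme
(neutral trials are dropped). Montage differences between datasets are
handled by an explicit `channel_map` from configured names to test-cohort
names; guessing electrode equivalences silently is deliberately not done.

For container I/O the package uses a portable JSON text container (samples
serialized at 17 significant digits, which round-trips IEEE doubles
bit-exactly) with dataset dialects expressed as label conventions:
SEED-style ordinal labels −1/0/1 at 200 Hz, DEAP-style per-trial valence
ratings in [1, 9] at 128 Hz binarized at the scale midpoint 4.5 (ratings
*above* 4.5 are positive; the boundary rating itself is negative, since it
is not above the midpoint — configurable), and LUMED-style binary labels at
500 Hz. The original MATLAB/pickle dataset containers are converted to this
container with a one-line `scipy.io`/`h5py` call outside R.

## The synthetic cohort generator

`generate_cohort` emulates the statistical structure the pipeline is
sensitive to, not the physiology. Each trial's signal per channel is a sum
of band-limited Gaussian noise components over the canonical EEG bands
(delta 1–3, theta 4–7, alpha 8–13, beta 14–30, gamma 31–50 Hz), weighted by
a per-class band signature; the defaults make the negative class
alpha-dominant and the positive class beta-dominant (weights 0.55 vs 0.17,
with a theta-dominant neutral class in the three-class scheme), a strong,
spectrally interpretable contrast. Band components are order-4 Butterworth
bandpasses of white noise, applied forward-backward and rescaled to unit
standard deviation; the rhythmic signal is scaled to 10 microvolts, a
typical scalp rhythm amplitude. Cross-subject non-stationarity is emulated
by a per-subject multiplicative gain `g_s ~ N(1, 0.1)`, an additive offset
`o_s ~ N(0, 1 µV)` and broadband sensor noise (sd 1 µV). Defaults: 5
subjects, 4 trials per class of 10 s at 200 Hz on the standard 9-channel
montage. The cohort is a pure function of its configuration seed.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: volume conduction and realistic channel covariance,
artifacts (ocular, muscular), label noise, within-session drift, 1/f
background structure, and the sheer feature-space complexity that motivates
a large pretrained backbone. The synthetic benchmark establishes that the
pipeline's machinery (windowing, augmentation, training, filtering,
subject-exclusion bookkeeping) recovers a recoverable signal across
simulated subjects; it says nothing about accuracy on SEED/DEAP/LUMED-scale
recordings.

Two properties connect the generator to the evaluation tests. First, its
classes are separable by construction: a nearest-centroid classifier on log
band-power features exceeds 90% within-subject window accuracy at the
default noise level (tested), so the end-to-end recovery benchmark is
demanding of the pipeline rather than vacuous. Second, the gain knob
produces a dose-response: raising `subject_gain_sd` from 0 through 1 to 1.5
degrades mean LOSO accuracy monotonically in the benchmark configuration
(tested over three seeds), reproducing the qualitative cross-subject
degradation that motivates subject-independent evaluation.

## Numerical and scale choices

* **Desk-scale benchmark sizes.** The test-suite and acceptance benchmarks
  run 3–5-subject cohorts (a few hundred windows) with a reduced dense head
  (128, 64) and minibatch 16. With only a handful of minibatches per epoch,
  the patience-limited run would otherwise see too few optimizer steps: an
  epoch of a 200-window cohort at batch 64 is 4 gradient steps, and
  patience-6 early stopping can end training after ~10 epochs. Batch 16 at
  these cohort sizes gives the optimizer the same order of step count per
  plateau that batch 64 gives at dataset scale. The full-scale defaults
  (1024-wide head, batch 64) remain the package defaults.
* **Determinism.** Every random stream (cohort generation, augmentation
  noise per window and slice, weight initialization, shuffling, splits) is
  derived from one seed through a multiplicative-congruential fold of stage
  and provenance identifiers, so any tensor or fold is reproducible in
  isolation and results do not depend on evaluation order.
* **Filters.** The optional recording bandpass is an order-6 zero-phase
  Butterworth (order 8 is numerically unstable in transposed direct form at
  EEG band edges; order 6 attenuates a 100 Hz tone below 3% RMS through a
  0.5–75 Hz band at 500 Hz). The generator's per-band filters are order 4,
  which is ample for shaping broadband noise.
* **Degenerate inputs.** Trials shorter than `N` yield zero windows; a
  single-class training set is an error; more channels than `N1` rows is an
  error (originals could not all be placed); label sequences shorter than
  the filter are handled by the shrinking edge windows.
* **Container precision.** JSON numbers are not bit-faithful for doubles at
  default precision, so the recording container serializes samples as
  17-significant-digit strings; round-trip identity is part of the test
  suite.

## Known limitations

* The surrogate backbone is a random-feature extractor; absolute accuracies
  with it are not comparable to a fine-tuned pretrained network, and
  backbone fine-tuning is not implemented (the pluggable `features_fn`
  contract is the extension point).
* No artifact handling: inputs are assumed pre-cleaned.
* Dataset adapters read the package's portable container only; parsing the
  original proprietary containers is out of scope.
* The subject-shift model (gain + offset) is crude by design; it produces
  the qualitative cross-subject degradation but not the spectral reshaping
  seen across real subjects.
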