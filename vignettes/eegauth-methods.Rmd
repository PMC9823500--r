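---
title: "EEG authentication with wavelet statistics: models, protocol and design notes"
author: "eegauth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG authentication with wavelet statistics: models, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegauth)
```

## The problem

Biometric user authentication from the electroencephalogram treats a short
multichannel EEG measurement as the credential: during *enrollment* a model
is trained on the legitimate user's signal; during *authentication* a new
measurement is accepted or rejected. Two model families matter in practice:

* **multi-class (binary) classifiers** — SVM, random forest, k-nearest
  neighbours — trained on the user's segments *and* impostor segments, and
* **one-class novelty detectors** — one-class SVM, isolation forest, local
  outlier factor — trained on the user's segments only, which is the
  deployable setting (impostor data is rarely available at enrollment).

`eegauth` implements the full pipeline — feature extraction, per-user
splits, six classifiers behind one contract, dimensionality reduction,
confusion/ROC evaluation — plus the experiment suite built on it:
baselines, per-channel and per-band ablation, the ν/contamination sweep,
and a hybrid cascade in which a one-class first layer labels the training
data of a supervised second layer.

## Feature extraction

Each channel of a recording sampled at 256 Hz is cut into consecutive,
non-overlapping **240 ms windows** (61 samples; the trailing remainder is
dropped). Every window is decomposed with a **five-level discrete wavelet
transform using the order-2 Daubechies wavelet**, giving detail
coefficients D1–D5 and the approximation A5, whose dyadic frequency ranges
at 256 Hz are the canonical brainwave bands:

| Band | Hz | Brainwave |
|------|------|-----------|
| D1 | 64–128 | high gamma |
| D2 | 32–64 | gamma |
| D3 | 16–32 | beta |
| D4 | 8–16 | alpha |
| D5 | 4–8 | theta |
| A5 | 0–4 | delta |

Eight statistics are computed per coefficient vector — maximum, minimum,
mean, standard deviation, variance, skewness, Shannon entropy, average
power — so a 14-channel montage yields 14 × 6 × 8 = **672 features** per
window; one channel contributes 48, one band 112.

Numerical conventions, where the method leaves room:

* **Window length.** 0.240 s × 256 Hz = 61.44; we use `floor`, 61 samples.
* **Boundary extension.** Half-sample symmetric extension (the edge sample
  is repeated), the convention shared by the mainstream wavelet toolboxes;
  the transform is realized as cached per-length filter-bank matrices, so
  a whole segment batch is two matrix products per level.
* **Five levels on 61 samples** exceeds the conservative max-level
  rule-of-thumb for a 4-tap filter; we follow the method as stated and
  accept boundary-dominated D5/A5 vectors (length 4). They still carry
  usable band-energy summaries.
* **Statistics.** Population (divide-by-n) standard deviation, variance
  and skewness; skewness is defined as 0 for a constant vector. Shannon
  entropy is taken on the normalized coefficient-energy distribution
  `p_k = x_k^2 / Σ x_j^2` in base 2 — the standard wavelet-entropy
  convention — and is 0 for a zero-energy vector. Both std and var are
  kept although redundant, because the feature set is defined that way.
* **A5 edges.** The approximation band after five halvings spans 0 to
  `fs/2^6` = 4 Hz (below D5's 4–8 Hz), which is what the filter-bank
  algebra and the brainwave table give.

## Enrollment/authentication protocol

All splits are per target user, with label 1 = legitimate. Multi-class:
80% of the user's segments train / 20% test, impostor segments drawn
uniformly without replacement from all other users and matched 1:1 in
every partition; 15% of the combined train set is carved out, stratified,
as validation. One-class: 80% of positives train (no negatives), test =
remaining 20% plus as many impostors. Features are z-score standardized
with train-fitted means and standard deviations only.

The "15% of the train set" rule is interpreted as 15% of the *combined*
(positive + negative) train pool; a positives-only reading would change
only the validation bookkeeping, not training. The positive 80/20 split
and the negative draw use independent sub-seeds, so repeated experiments
can redraw impostors while keeping the positive partition fixed — that is
exactly what the stability check varies.

## Classifiers

All six kinds sit behind one `train_model()` / `predict()` contract
(labels in {0, 1}; continuous scores only for the multi-class kinds, since
one-class models emit hard accept/reject decisions).

* **SVM** (RBF kernel): `C` and `gamma` tuned by 10-fold cross-validated
  accuracy over `C ∈ {0.1, 1, 10, 100, 1000}` and
  `gamma ∈ {auto, scale, 0.001, 0.01, 0.1, 1, 10, 100}` (`auto` = 1/p,
  `scale` = 1/(p·Var(X))). The selection metric and tie-breaks are not
  prescribed by the method, so we pick accuracy with ties broken toward
  smaller `C`, then smaller resolved `gamma` — the less complex model.
  Scores are decision values (not Platt probabilities, which would add
  their own cross-validation randomness).
* **Random forest**: 500 trees, unlimited depth. Scores are class-1 vote
  fractions.
* **KNN**: k = 25, Euclidean distance; scores are neighbour vote
  fractions.
* **One-class SVM**: RBF, the ν parameter as the rejection budget,
  `gamma = scale`.
* **Isolation forest**: 500 trees on subsamples of 256, anomaly score
  `2^(-E[h]/c(ψ))`; implemented in C++ inside the package. The decision
  threshold is the `1 - contamination` quantile of the *training* scores,
  so the contamination dial is exact on the training set.
* **Local outlier factor**: k = 25, **novelty mode** — reachability-based
  local densities are fitted on training points only and unseen points are
  scored against that reference. The verification protocol requires this:
  test segments must never be part of the neighbourhood structure they are
  judged against. Thresholding mirrors the isolation forest.

A note on the ν dial: for the quantile-thresholded detectors the number of
training points flagged as outliers is non-decreasing in contamination *by
construction*. For the one-class SVM, ν bounds margin errors inside the
optimization, not predicted rejections, and small non-monotonicities at
low ν are a real property of the fitted boundary; the test suite checks
strict monotonicity for isolation forest and LOF and a tolerant version
for the one-class SVM.

## The hybrid cascade

The deployable one-class setting can be sharpened with a supervised second
layer that never sees ground-truth impostor labels: (1) train the
one-class model on part of the user's data; (2) let it label a held-out
pool of positives plus impostors; (3) train a multi-class model on those
*assigned* labels; (4) evaluate against ground truth on a third, disjoint
pool with a fresh impostor draw.

The method's description stops after step (3); printed metrics, however,
require ground truth unseen by both layers. The minimal design that makes
the evaluation well-posed is a three-way split of the user's positives —
**0.6 / 0.2 / 0.2** (one-class train / hybrid train / final test), config-
exposed — with disjoint impostor draws for the two labelled pools. The
default layers are isolation forest (contamination 0.3) → random forest,
and the named feature configurations I–V select band/channel subsets
(Configuration III = D1 on all channels, 112 features). Configuration II
is implemented from its stated channel list (7 channels, hence 56
features) rather than its stated feature count (64), which is
inconsistent with 7 × 8.

An audit trail of row ids verifies that the final-test pool is untouched
until step (4), and an `oracle_first_layer` mode replaces the one-class
labels with ground truth, which reduces the cascade to ordinary supervised
training — the test suite asserts that equivalence exactly.

## The synthetic cohort

The real measurements behind this kind of study are private, so the
package ships a seeded generator whose cohorts exercise every downstream
stage. For user *u*, channel *c*, band *b*:

* a fixed identity offset `z[u,c,b] ~ N(0,1)` is drawn once per user;
* each one-second block gets amplitude
  `a = base_b · exp(identity_strength · z · 1[b ∈ identity_bands] +
  within_user_jitter · w)`, `w ~ N(0,1)` fresh per block;
* the channel signal is the sum over bands of `a` times a unit-variance
  band-limited carrier, plus `background_level` times 1/f noise.

Carriers are synthesized by spectral masking of white Gaussian noise
(zero every FFT bin outside the band, invert, re-standardize): exact
confinement with no filter-design ambiguity. Implementation-wise one
carrier spans the whole recording and the blockwise amplitudes multiply it
as a step envelope — equivalent to per-block synthesis for everything the
features see, at a fraction of the FFT cost. Amplitudes are redrawn per
second, slower than the 240 ms window, so intra-user variation mimics
nonstationary EEG without destroying per-segment identity. The delta
carrier's nominal 0 Hz lower edge is realized as 0.5 Hz to avoid a DC
spike; the feature side still labels A5 as 0–4 Hz. The per-band base
amplitudes follow a 1/f-like profile (larger for lower bands), matching
generic EEG spectra; they are config entries, not estimates of any real
dataset.

**Calibration.** No quantitative description of inter-subject EEG
variability was available to copy, so the identity scale is a free knob
chosen once: `identity_strength = 0.3` with `within_user_jitter = 0.25`
and `background_level = 0.6` puts a 500-tree random forest at ≈0.97
accuracy and an isolation forest at precision ≈0.87 / recall ≈0.57 on a
pilot cohort — the performance regime published EEG-biometric studies
report.
Setting `identity_strength = 0` makes users exchangeable (classifiers fall
to chance), and `identity_bands = "D1"` concentrates identity in
64–128 Hz, which the ablation experiment must recover.

**What the generator is not.** There are no evoked potentials, eye
blinks, electrode artifacts, or session effects; identity lives purely in
stationary band-power signatures. Passing tests therefore demonstrate
that the pipeline recovers the structure this model injects — not that it
would reach the same numbers on real EEG.

## Evaluation

Precision, recall, F1, accuracy and false positive rate follow the usual
confusion-table definitions with the legitimate user as the positive
class; ratios with a zero denominator return 0 with a warning so that
degenerate reject-all sweeps still tabulate. ROC curves are built by
threshold enumeration over the unique scores; AUC is the trapezoid area;
the **equal error rate** is the point where the false positive rate equals
the false rejection rate, linearly interpolated on the ROC polyline.
AUC/EER are reported only for score-producing (multi-class) models.
Cohort results are macro-averages over users. Per-fit wall times are
recorded but never asserted on — they are hardware, not method.

## Problem sizes used by the checks

The shipped tests and the `scripts/acceptance.R` runner use modest cohort
sizes while keeping the per-user segment counts at study levels:
full-length recordings (120 s ≈ 503 segments per user; 61-sample windows)
with 6–10 users. The contamination sweep uses 10 users; the
ablation-recovery and cascade checks use 6 users over five seeds; the
acceptance script uses 8. Where a check compares the cascade against its
one-class layer, full-length recordings matter: halving them halves the
hybrid-train pool and visibly destabilizes the second layer — consistent
with the protocol's assumption of roughly two minutes of enrollment
signal.

## Known limitations

* Only the `db2` wavelet is implemented; the decomposition is exact for
  the symmetric-extension convention it declares, and other boundary modes
  are not offered.
* EDF input is not implemented; recordings enter via the channels-as-
  columns CSV reader or in memory. (The synthetic cohort writer emits that
  CSV plus a JSON manifest.)
* The chi-squared selector uses the class-conditional feature-sum
  statistic on min-max-scaled features — the common feature-selection
  form; a discretized variant is not implemented.
* One-class scores are deliberately not exposed through `predict()`; the
  evaluation vocabulary for those models is label-based by design.
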