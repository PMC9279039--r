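---
title: "Resting-state features, capsule classification and group statistics: methods"
author: "capsfmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state features, capsule classification and group statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`capsfmri` implements a complete desk-scale pipeline for two-class
resting-state fMRI classification (depression vs. control in the motivating
application, but nothing in the code is disease-specific): per-voxel and
per-region feature extraction, a capsule-network classifier, multi-feature
ensemble fusion, and voxelwise group-difference cluster reporting. The data
objects are S4 classes: a `TimeSeriesVolume` is one subject's 4D array
(x, y, z, t) plus the repetition time TR; an `AtlasParcellation` is an
integer label volume (0 = background, labels 1..N are the regions, as in the
116- or 246-region anatomical atlases this emulates); a `FeatureMap` is a 3D
per-voxel scalar map. All indexing is 1-based with the time axis last; that
single convention is used by every module.

Volumes containing NaN or Inf are rejected at load. Every downstream
statistic divides by a variance or an amplitude sum, so missing data has no
well-defined propagation; failing fast beats silently masking.

# Preprocessing

The computable residue of a standard resting-state standardisation pipeline
(the data this package sees are already in atlas space, so registration and
normalisation are out of scope):

* **Linear detrending** — ordinary least squares per voxel; output series
  have zero mean and zero slope. Idempotent.
* **Band-pass filtering** — a frequency-domain boxcar: forward DFT, zeroing
  of every bin outside the closed band, inverse DFT. The conjugate-symmetric
  mask keeps the output exactly real, makes the filter idempotent, and makes
  its transfer function testable bin by bin, which an IIR design would not
  be. The default band is 0.01–0.08 Hz, the conventional low-frequency
  window for resting-state BOLD fluctuations.
* **Gaussian smoothing** — separable, border-renormalised so constants are
  preserved; off by default (`fwhm = 0`). Regional homogeneity must see
  unsmoothed data — smoothing manufactures local synchrony — so the pipeline
  never smooths ReHo input even when smoothing is enabled globally.

The wiring between preprocessing and features is fixed and tested: the
spectral features (ALFF, fALFF) consume detrended but **unfiltered** series,
because fractional ALFF's denominator is the amplitude over the whole
spectrum and is meaningless after band-passing (on band-passed input fALFF
is identically ~1). The correlation features (FC, DC, ReHo) consume
detrended, band-passed series.

# Features

* **Functional connectivity (FC).** Region time series are the arithmetic
  mean over each region's voxels at each time point (the mean, not the bare
  sum — the sum would scale with region size and break comparability across
  regions). The FC matrix is the N×N Pearson correlation matrix,
  symmetrised exactly with unit diagonal; the feature vector is the strictly
  lower triangle in row-major order (2,1), (3,1), (3,2), ..., a documented
  fixed order of length N(N−1)/2 that is lossless given symmetry. No Fisher
  z-transform is applied. Constant region series are an error naming the
  region, never a silent zero.
* **Degree centrality (DC).** Per voxel, the count of other voxels whose
  correlation exceeds 0.25 on the **signed** scale (r > 0.25, strictly; an
  anticorrelated voxel contributes nothing). That is the conventional
  binarised-adjacency definition; `absolute = TRUE` switches to |r| > 0.25
  for users who want the magnitude variant. Zero-variance voxels get DC = 0
  and are flagged.
* **Regional homogeneity (ReHo).** Kendall's coefficient of concordance W
  over the K series of a voxel and its neighbours (27, 19 or 7, including
  the centre): with R_t the rank sum at time t,
  W = (Σ R_t² − T R̄²) / ((1/12) K² (T³ − T)) ∈ [0, 1].
  Ranks are midranks without a tie-correction term — ties have measure zero
  for continuous data and the omission is documented rather than patched.
  Boundary voxels use the truncated neighbourhood actually inside the grid;
  padding would invent data, truncation keeps W well defined.
* **ALFF / fALFF.** The one-sided DFT amplitude |X[h]| is computed per
  voxel; ALFF is the amplitude sum over bins whose frequency h·fs/T lies in
  the closed 0.01–0.08 Hz band, and fALFF divides it by the amplitude sum
  over all bins excluding the DC bin (a detrended series has none, but the
  exclusion is kept explicit and switchable). The amplitude sum Σ|X[h]| is
  the primary definition; `powerMode = TRUE` restores the squared-amplitude
  variant Σ|X[h]|² for both maps. A band containing no DFT bin for the given
  (T, fs) is a configuration error that names the bin grid. fALFF of a
  constant series is undefined; such voxels are set to 0 and flagged with a
  warning.

Every feature is validated in the test suite against an independent
brute-force oracle (two-pass Pearson sums, all-pairs threshold counting,
explicit rank-sum W, direct complex-exponential bin enumeration) to 1e−10
on batches of random volumes.

# Capsule classifier

The classifier is a capsule network: a ReLU convolutional stem, a
convolutional primary-capsule layer whose channels are read as 8-dimensional
vectors and squashed (v = s·‖s‖/(1+‖s‖²), mapping into the open unit ball),
and one 16-dimensional class capsule per class. Coupling between primary and
class capsules is set by dynamic routing by agreement: logits start at zero,
coupling coefficients are the per-input-capsule softmax of the logits, class
capsules are squashed coupling-weighted vote sums, and logits are
incremented by the vote–output scalar product. Class scores are the class
capsule lengths in [0, 1), and training minimises the margin loss

L = Σ_p [ T_p max(0, 0.9 − a_p)² + 0.5 (1 − T_p) max(0, a_p − 0.1)² ],

with margins m+ = 0.9 and m− = 0.1 and down-weight λ = 0.5 on the negative
classes. There is no reconstruction regulariser: the stated objective is the
margin loss alone.

Design choices that were genuinely open, and how this package resolves
them:

* **Input representation.** Each subject's 3D feature maps are reduced to
  the axial mid-slice and stacked as channels (three orthogonal mid-slices
  are available via `slices =`). A 2D stem keeps the model desk-scale and
  the synthetic cohorts place signal in regions that intersect the
  mid-slice. Channels are z-scored within subject so the physical scale of
  ALFF (tens to hundreds) cannot dominate fALFF (a ratio in [0, 1]);
  switchable via `zscore`.
* **Architecture constants.** The canonical capsule stem (256 conv
  channels, 9×9 kernels, 32 primary-capsule channels) is the literal
  default of `capsNetConfig()`, but it cannot tile a 12×12 atlas slice, so
  experiments use `defaultCapsConfig()`: a 32-channel 5×5 stem, a 4×4
  stride-2 primary layer with 4 capsule channels of dimension 8, 16-dim
  class capsules and 3 routing iterations. All of it is configuration, and
  a configuration whose kernels do not tile the input is rejected at
  construction rather than failing inside the forward pass.
* **Two classes.** The architecture's historical 10-category head is an
  artefact of its origin; `nClasses` defaults to 2 (patient vs control).
* **Optimisation.** Adam (β₁ = 0.9, β₂ = 0.999) on the mean margin loss,
  default 30–50 epochs of batch size 16, learning rate 2e−3 at desk scale.
  Everything — initialisation, shuffling, updates — runs off one seeded RNG
  stream, so training is bit-reproducible.
* **Gradient through routing.** The backward pass treats the coupling
  coefficients produced by the final routing iteration as data-dependent
  constants: gradients flow through the vote-weighted sums, the
  transformation matrices, the squashes and the convolutions, but not
  through the logit-update recursion. This is a standard simplification in
  capsule implementations; the package's own finite-difference check
  confirms the gradient is exact (≈1e−7 relative) when `routingIters = 1`
  and the training criteria confirm it is more than sufficient at 3
  iterations. The margin-loss gradient itself is verified analytically
  against finite differences at 1e−5.

# Ensemble and evaluation

Per-feature models are fused by weighted averaging: each member's score
vector is first normalised to sum to 1 (capsule lengths are not
probabilities and do not), fused scores are the weighted sum, and the
prediction is the argmax with ties broken toward class 0 — an exactly split
vote is reported as the control class, a documented deterministic rule.
Weights default to uniform.

Three metrics are reported, with class 1 (patient) positive: **correct
rate** (TP+TN)/n, **recall** TP/(TP+FN) and **precision** TP/(TP+FP). This
naming maps the field's loosely-used triple ("correct rate", "recall",
"accuracy") onto the only reading in which all three are distinct; the
third number is precision and is labelled as such everywhere in this
package. Zero-denominator ratios are NA with a warning, never a silent 0.

The experiment protocol (`runExperiment`) is a single stratified 80/20
split: one capsule model per feature trained on the common training set,
members and their ensemble evaluated on the common held-out set, all seeds
derived from one master seed. No cross-validation scheme is implied by the
source material; the single-split protocol is this package's own, and it is
labelled as such.

# Group statistics

`voxelwiseTTest` computes the per-voxel two-sample t statistic on any
per-subject scalar maps — pooled-variance by default (the classic
SPM-style choice), Welch by switch. `extractClusters` thresholds |t|,
splits by sign, labels connected components (26-, 18- or 6-connectivity),
drops clusters below the extent threshold and reports voxel count, peak T,
peak Z and peak coordinates per cluster. Z is the standard-normal quantile
of the t tail probability, computed on the log scale so |t| in the tens
does not saturate, signed like t, with Z(0) = 0. No multiple-comparison
correction is applied by default, mirroring conventional uncorrected
cluster tables; `voxelwiseFdr` provides the Benjamini–Hochberg-corrected
voxel map for the corrected path. Cluster volumes in mm³ are reported when
a voxel size is supplied, since extent in voxels is the primitive quantity.

# Synthetic cohorts: what they emulate and what they do not

No patient cohort is distributable, so the package carries a generator
whose defaults emulate the motivating study's scale: 70 patients and 30
controls, TR = 2 s, 128 time points, a 12×12×12 grid of 8 contiguous block
regions standing in for an anatomical parcellation. Each subject's voxel
series is white Gaussian noise (sd 1) plus a per-region low-frequency
oscillation — a sum of 3 sinusoids with frequencies drawn uniformly in
0.01–0.08 Hz, random phase, per-sinusoid amplitude 0.5 (chosen once so the
oscillation carries roughly a third of baseline series variance, a
realistic BOLD-band share). Patients differ through three orthogonal
knobs, each applied only when the label is 1:

* `effectAlff` multiplies the in-band oscillation amplitude in the affected
  regions by (1 + effectAlff) — moves ALFF/fALFF;
* `effectFc` mixes a common oscillation into every affected region with
  weight w (region oscillation becomes (1−|w|)·own + w·shared) — moves
  inter-region coupling;
* `effectReho` replaces a fraction ρ of each affected voxel's noise with a
  region-shared component ((1−ρ)·own + ρ·shared) — moves local synchrony.

The default affected regions (5 and 6) intersect the axial mid-slice the
classifier sees. All random draws happen in a fixed order regardless of
label or effect size, so a control and a patient with the same subject seed
differ only through the effects, and an all-zero-effect cohort is literally
label-free data — the basis of the null guards. Everything is deterministic
given (cohort seed, subject index).

The generator deliberately omits hemodynamic response shape, autocorrelated
(AR) noise, head motion, physiological cycles and scanner drift. Passing
tests therefore demonstrate that the implementations are correct and that
the pipeline recovers known injected effects under clean conditions; they
do not demonstrate clinical-grade performance on real scans, and the
headline accuracies on these separable synthetic cohorts should be read as
recovery checks, not benchmarks.

# Validation protocol and problem sizes

The test suite validates every feature against brute-force oracles on ~100
random volumes up to 6×6×6×64; trains on a single-channel cohort
(effectAlff = 3, 40 + 40 subjects, 12³ × 128) expecting held-out accuracy
at least 0.9; fuses fALFF + DC + ALFF members on a three-channel cohort
(effectAlff = 3, effectFc = 0.8, effectReho = 0.6) expecting a perfect
held-out split; checks that all-null cohorts yield chance-level accuracy
(inside the 95% binomial interval around 0.5) and empty cluster tables at
t > 3.0 / extent ≥ 10 in at least 9 of 10 seeds; recovers an injected
region as the top cluster with Dice ≥ 0.5 at 30 subjects per group; and
re-runs the full simulate → extract → train → evaluate pipeline twice to
verify bit-identical outputs. Null-guard cohorts use balanced groups: with
the study's 70/30 imbalance a majority-class predictor sits at 0.70 and
would confound a chance-level test against 0.5. These problem sizes are the
package's chosen validation scale — large enough for the statistics to be
stable, small enough to run routinely.

# Known limitations

* The simulation's stationarity and whiteness are idealisations (above).
* DC is computed over the whole grid; a tissue mask can be emulated by
  zero-filling, but no mask argument is threaded through.
* The routing-gradient simplification means training is not following the
  exact gradient for `routingIters > 1`; at these problem sizes it has no
  observable cost.
* Maps are not standardised against a group template (no z-maps / mALFF);
  within-subject z-scoring happens only at the classifier input.
* The single-split protocol reports one draw, not a cross-validated
  distribution; `stratifiedSplit` is exposed so users can loop seeds.
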