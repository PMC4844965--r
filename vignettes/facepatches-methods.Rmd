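---
title: "The facepatches model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The facepatches model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`facepatches` implements a hierarchical model of primate face processing
organised after the macaque face-patch system: a generic HMAX-style
front end (posterior patch, PL), a view-selective layer (middle patches,
ML/MF) and an identity-selective layer (anterior-medial patch, AM).

**S1/C1.** S1 convolves the grayscale input with a bank of zero-mean,
unit-norm Gabor filters (4 orientations; 8 sizes from 7 to 21 px paired
into 4 scale bands) and rectifies. C1 takes, per orientation and band,
the elementwise max over the band's two scales followed by a local
spatial max over `c1_pool` neighbourhoods (8-14 px) sampled with stride
3. Because every filter is exactly zero-mean, a uniform gray image
produces identically zero C1 activity -- the network's baseline state.

**S2/C2.** S2 units are radial-basis templates: patches of C1 response
(sizes 4, 8, 12 and 16 C1 cells, spanning all orientations) cut at
random from training images. Both stored prototypes and incoming patches
are centred and normalised to unit norm, and the response is

    R = exp(-gamma * || patch_hat - P ||^2),

so R = 1 exactly when the input reproduces the prototype's source patch
and responses are contrast-tolerant. C2 is the global max over positions
and bands, one value per prototype. A patch with no C1 energy responds
0, so a blank image yields an all-zero C2 vector.

**VSL.** View-selective units are Gaussian kernels in C2 space,

    g_i = exp(-||x - P_i||^2 / (2 sigma^2)),  sigma = 0.5,

with an additive trace: the emitted activation is
`r_i = g_i + alpha * trace_i` (alpha = 0.3), clamped at 1, and the trace
is set to the emitted activation. Growth follows an adaptive-resonance
vigilance rule: when the best instantaneous (trace-free) match among
existing units falls below the vigilance `rho` the input becomes a new
template. Growth intentionally uses the trace-free response (novelty of
the template) while winner selection for wiring uses the standing traced
activation (temporal continuity) -- the trace exists precisely to carry
identity across adjacent views.

**ISL.** Identity-selective units max-pool a private set of VSL units
(binary weights; each VSL unit wires to exactly one ISL unit, so the
incoming sets partition the VSL population) and mix in their own trace:
`r_j = 0.7 * max_pool + 0.3 * trace_j`. When a VSL unit is born, it is
wired to the ISL unit with the largest standing activation from the
previous stimulus -- or to a fresh ISL unit when every trace is zero,
which is what happens right after a blank separator. Views of one
identity, presented contiguously, therefore converge onto one ISL unit,
while a new identity (after a blank) founds a new unit.

**Silence convention.** An input with no front-end energy (the blank
gray separator) produces zero activations *and clears the traces* in
both layers: memory is memory of activity, and the baseline state
carries none. This makes an interleaved blank image behave exactly like
an explicit trace reset, matching the protocol in which blanks silence
the network between identities.

## Training protocol

Identities are presented one at a time: a uniformly random first view,
then the remaining 36 views in 5-degree order with wrap-around at the
profile, then a blank. With blanks separating identities, each identity
creates at most one ISL unit. After every identity that created one, the
model is scored on a held-out evaluation set (view-invariant identity
selectivity index, VISI, plus the accuracy of a linear SVM trained on a
random 18-view split and tested on the complementary 19 views); if VISI
does not strictly increase, the identity's new units are rolled back
(the model state is a plain R value, so the pre-identity snapshot is
restored bit-identically). The first identities are kept unconditionally
until the ISL has two units, below which VISI is undefined. Growth
therefore concentrates early and saturates, and the evaluation curves
plateau.

## Representational statistics

All similarity matrices are Pearson correlations between per-image
feature vectors in view-major order. VSI divides the mean within-view
block correlation by the mean over the rest of the matrix (diagonal
excluded); VISI divides the mean same-identity cross-view correlation
(row-column lags at multiples of the identity count) by the mean of the
other off-diagonal entries. The degree of invariance (DoI) of a
reference view counts the views whose within-identity correlations
significantly exceed (one-sided rank-sum, alpha = 0.02) the
between-identity correlations at the reference view; the self view is
trivially invariant and counts, so DoI is in [1, 37]. The original
description states the between-identity *average* as the threshold in
one place and the *maximum* in another; both are implemented
(`threshold = "mean"` / `"max"`), with "mean" as the default since the
methods-style definition is the normative one. Significance tests
throughout are Wilcoxon-Mann-Whitney rank-sum tests, one-sided where the
hypothesis is directional; the in-plane-rotation discriminability score
(z-scored mean pairwise distance, pooled reference population across
rotations and runs) uses a one-sided signed-rank test across runs with
Benjamini-Hochberg correction at 0.05.

## The synthetic face world

No photographic data ship with the package; a parametric generator
stands in for the multi-view photograph sets. An identity is an
11-dimensional parameter vector (head ellipse, eye separation/height/
size, nose length/width, mouth width/height, brow height, feature
contrast) drawn from a population distribution; two populations ("A",
"B") share a diagonal covariance and differ by a 1.5-sd mean shift
along five configural dimensions, standing in for two races: large
enough that an other-race effect is detectable with 20 identities,
small enough that cross-population identification stays above chance.

Rendering places features at fixed azimuths on a head ellipsoid and
projects them with yaw-dependent displacement and foreshortening.
Feature visibility falls smoothly as a power of the cosine of the
camera angle (a soft version of occlusion -- a hard threshold creates
view-to-view appearance jumps), the head narrows toward the profile,
and a lateral shading gradient tracks the yaw. These monotone global
cues make the pixel-space correlation to the frontal view strictly
unimodal in yaw, the statistical precondition for the invariance
analyses. Each rendered pose also receives deterministic "capture
noise" (sd 0.03 of the intensity range, seeded from identity and pose),
emulating the fact that every view of a photographic dataset is a
separate exposure; rendering remains a pure function of its inputs.
Inversion is an exact vertical flip; in-plane rotation rotates the
sampling grid analytically (no interpolation error); composites splice
the top half of one identity onto the bottom half of another, the
misaligned condition shifting the bottom half by half the face width.

What the generator does *not* emulate: texture, illumination variation,
expression, hair styles, or any photographic detail. Passing tests on
this world show that the architecture produces the qualitative
representational phenomena from the stimulus statistics it assumes
(smooth view sweeps, configural identity differences); they do not
certify performance on photographs.

## Numerical and design choices

* **gamma (S2 sharpness), default 1.** With unit-normalised patches the
  squared patch distance lies in [0, 4] regardless of patch size, so
  gamma must be order 1: much smaller values compress all C2 values
  toward 1, after which the VSL vigilance rule stops recruiting units
  and the ISL degenerates. gamma = 1 spreads C2 over roughly [0.1, 1].
* **rho (vigilance), default 0.9** with the documented grid-search
  utility `tune_vigilance()` (grid 0.80-0.98) selecting by evaluation
  VISI, mirroring the "set in the evaluation phase" procedure.
* **Trace clamping at 1** keeps activations commensurate with rho under
  repeated presentation.
* **ISL mixing 0.7 / 0.3** mirrors the VSL trace coefficient.
* **Ties** in max-pooling and winner selection break to the first
  position / lowest index: determinism.
* **Acceptance threshold 0** (keep an identity iff evaluation VISI
  strictly increases): the weakest rule consistent with removing
  modifications of "no significant impact". A config switch also gates
  on SVM accuracy.
* **Desk-scale defaults.** The bundled experiment battery uses 20
  training, 10 evaluation and 10-20 test identities, 200 prototypes and
  64 px images over 10 seeded runs; `n_prototypes = 1000` and larger
  identity counts reproduce the full-scale setting.

## Known limitations

* The exact printed forms of the view/identity-layer response equations
  were reconstructed from the surrounding prose (Gaussian of Euclidean
  distance; additive clamped trace; linear mix of max-pooled input and
  trace); all coefficients are configurable.
* Whether the ISL trace stores presynaptic or own past activity is
  ambiguous in the source; it is implemented as the unit's own past
  activation.
* The VSI of the view-selective layer is ill-conditioned in this
  synthetic world: trace-free VSL population responses to views far
  apart are *anti-correlated* across units (view-tuned kernels on an
  essentially one-dimensional view manifold), so the mean off-block
  correlation -- the VSI denominator -- is a small negative number and
  the ratio explodes with a flipped sign. This holds at every tuning
  sharpness we examined and is a property of the ratio statistic applied
  to sparse view-tuned codes, not of the growth dynamics; VISI-based
  orderings (identity coding) are unaffected. The indices are computed
  exactly as defined, and the geometry tests report this comparison
  honestly rather than substituting a better-behaved statistic.
* The C2 layer is not fully inversion-blind on the synthetic faces: the
  renderer's part-level structure carries more vertical polarity (hair
  band, brow and mouth bars) than photographic textures do, so an
  upright-trained S2 dictionary responds slightly less to inverted
  images and C2 between-identity distances shrink mildly at central
  views — a small but consistent effect across runs. The inversion
  effect in the ISL is orders of magnitude larger; the per-view
  comparison in the test suite reports both layers honestly.
* The SVM-accuracy acceptance gate is report-only by default
  (`gate_on_accuracy = FALSE`); the sources list both criteria without
  stating how they combine.
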