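---
title: "Methods: remora-swarm optimization of a small convolutional classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: remora-swarm optimization of a small convolutional classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models
and procedures it implements, the parameters that matter, the choices
made where the design was genuinely open, and what the test suite does
and does not establish. It states no empirical number that the tests or
the acceptance script do not themselves compute.

## 1. Problem setting

Four CT texture classes — three carcinoma appearances and a normal
class — are to be distinguished from single 8-bit grayscale slices.
Rather than hand-picking a convolutional architecture, the package
treats the classifier's *structure* (how many convolution, pooling and
fully connected layers) and its shared *layer parameters* (strides,
window sizes, padding flags, filter and neuron counts) as an
11-dimensional integer genome and searches it with a swarm
metaheuristic, using validation accuracy as fitness.

## 2. The remora optimizer

A population of N candidate positions ("remoras") minimizes an
arbitrary objective over a box. Each remora carries a host flag
H ∈ {0, 1} deciding its move:

* **Whale ride (H = 0), exploitation.** With
  `a(t) = −(1 + t/Tmax)` decaying linearly over `[−1, −2]`, a spiral
  exponent `α = u(a − 1) + 1` (u uniform) and elementwise distance
  `d = |r_best − r|`, the move is `d e^α cos(2πα) + r`. Near the elite
  (`d → 0`) this is a contraction; early in the run it oscillates.
* **Sailfish follow (H = 1), exploration.** The move
  `r_best − (u (r_best + r_rand)/2 − r_rand)` spans the segment from
  the midpoint `(r_best + r_rand)/2` out past `r_best + r_rand`.
  `r_rand` is a *fresh uniform location in the box*, not another
  remora's position. This reading matters: with remora-positions the
  swarm collapses onto the elite and, on the piecewise-constant
  landscapes produced by integer decoding, stops discovering new cells
  (the structure-recovery check then succeeds in only ~4/20 runs,
  versus 19–20/20 with uniform locations, while sphere convergence is
  unchanged). The uniform reading also keeps a constant fraction of
  the evaluation budget exploratory at any stage of the run.
* **Experience attack.** After moving, the remora probes
  `r_att = r' + (r' − r_pre)·z`, z standard normal, along its own
  displacement since the previous generation. If the probe *strictly*
  improves the remora's fitness it is adopted and H is redrawn
  uniformly — the minimal "host change" rule consistent with a
  tentative one-step test.
* **Host feeding.** Otherwise the remora takes the damped local step
  `ω(t) B (r' − C r_best)` with `B = 2Vu − V`, `V = 2(1 − t/Tmax)`,
  and remora factor `C = 0.1`. The inertia weight
  `ω(t) = 0.9` while `t < a_frac · Tmax` (default `a_frac = 0.5`) and
  `1/(1 + exp(10 t/Tmax − 2))` afterwards — a sigmoid that continues
  the schedule continuously downward from ≈0.047 to ≈3.4·10⁻⁴. ω damps
  only the host-feeding increment, the single velocity-like term in
  the dynamics; applying it to the whale or sailfish moves would scale
  absolute positions, not steps.

Bookkeeping choices: every proposed position is clipped to the box
before evaluation; the elite updates only on strict improvement (ties
keep the incumbent, for stability); one uniform draw per move, one
normal draw per probe, a single seeded generator for the whole run.
The optimizer snapshots and restores the global RNG state around each
objective call, so objectives that seed their own RNG (CNN training
does) cannot perturb the swarm's stream. Traces record the elite
fitness after initialization and after every iteration, hence are
non-increasing by construction.

Defaults (population 50, 100 iterations, bounds ±10) follow the
published simulation settings; the CNN search phases use their own
smaller desk-scale budgets (section 5).

## 3. Preprocessing

*Impulse filter.* Pixels exactly at 0 or 255 are treated as
salt-and-pepper corruption and replaced by the rounded mean of the
non-extreme pixels in their (default 3×3) window; a fully extreme
window falls back to the plain window mean. Non-extreme pixels are
untouched, so the filter is idempotent once extremes are gone and is
not a blur.

*Adaptive histogram equalization.* Classical rank/CDF equalization per
tile (default 8×8 grid): intensity v maps to
`floor(cdf(v)/n_tile · 255)`, where `floor` (not `round`) makes an
exactly half-filled CDF map to 127 — the convention the frozen
examples use. Tile mappings are bilinearly blended between the four
surrounding tile centers, which removes seams; border pixels use the
nearest tiles. A tile with a single unique value maps to itself —
plain equalization would send a flat region to white. No clip limit by
default (contrast limiting is available as an optional argument), as
nothing in the modelled procedure calls for one.

## 4. Features

14 values per image, in fixed order:

* **Haar sub-bands (4).** One level of the orthonormal 2-tap Haar
  transform, columns then rows (odd extents edge-replicated first);
  each sub-band is summarized by its mean absolute coefficient. The
  transform is exactly invertible and energy-preserving, which the
  tests verify against an explicit transform-matrix oracle. On a
  constant image of value c the LL summary is 2c and the details
  vanish.
* **GLCM statistics (5).** Gray levels quantized to L = 8 by
  `floor(v·L/256)`; co-occurrences counted at distance 1 for angles
  0°/45°/90°/135°, each accumulated symmetrically and normalized; the
  five Haralick statistics (contrast, correlation, homogeneity
  `Σ p/(1+(i−j)²)`, entropy in bits with 0·log 0 = 0, energy = angular
  second moment) are averaged over the four angles. A zero-variance
  matrix is defined to have correlation 1 (a constant field is
  perfectly self-correlated). All settings are exposed in
  `feature_config()`.
* **Histogram moments (5).** Population central moments: mean,
  variance m₂, SD, skewness m₃/m₂^1.5 and *excess* kurtosis
  m₄/m₂² − 3, so a Gaussian image reads 0 — chosen for testability; a
  constant image returns 0 for both shape statistics by convention.

## 5. The classifier and the two-phase search

*Genome → network.* The structure triple (nc, np, nf) and the 8 layer
values decode from real positions by flooring and clamping into their
ranges, so any real vector is a valid genome; continuous search boxes
extend one unit past each maximum so every integer (e.g. 64 filters)
is reachable. The network alternates conv→pool pairs for
min(nc, np), then surplus convolutions, surplus poolings, nf fully
connected ReLU layers of `op` units, and a 4-way softmax head. All
convolutions share (c_fs, c_nf, c_ss, c_pp) and all poolings
(p_fs, p_ss, p_pp) — the 8-slot phase-2 genome cannot express
per-layer values. A layer whose valid-padding window no longer fits
the current extent is skipped (counted, never fatal), so assembly is
total over the genome space. The published range for `op` is a single
value, which cannot hold a classifier head; it is treated as a
misprint and widened to 4–128, with the head always forced to K = 4.

*Training.* Plain mini-batch SGD (no momentum — gradient descent is
the procedure being modelled) on softmax cross-entropy; learning rate
0.01, batch 16, 5 epochs per fitness probe. Feature inputs are
z-scored with training-set statistics stored in the model (the raw
features span five orders of magnitude; plain SGD cannot train
otherwise); image inputs are scaled to [0, 1]. The softmax head is
zero-initialized so an untrained network predicts the uniform
distribution — its loss on balanced data is exactly log 4, a useful
anchor. Hidden layers use He initialization. Divergence (non-finite
loss) is an error at the training API and is scored as worst-case
fitness (accuracy 0) inside the search. The 1-D layer kernels are
compiled (im2col/col2im in C++, arithmetic in BLAS); the optional 2-D
image mode stays in R and is intended for small images.

*Search.* Phase 1: 5 remoras over the 3-dim structure box, with the
layer genome pinned at the floored midpoints of its ranges so
structure fitness values are comparable. Phase 2: 10 remoras over the
8-dim layer box with the structure fixed — 5 seeded inside the decode
cells around those midpoints (one small uniform jitter each), 5
uniform. Fitness is the negated accuracy on an inner 80/20 validation
slice of the training split (the procedure never names a validation
set; an inner split is the standard way to keep the test split
untouched, and the result records exactly which rows fitness saw).
Fitness values are memoized per decoded genome — decoding is
many-to-one and training is seed-deterministic, so memoization only
skips recomputation. Desk-scale defaults run 10 iterations per phase;
the published 100 is one argument away. The winning pair is retrained
on the full 80% training split for `final_epochs` (default 30, longer
than the 5-epoch probes since this model is kept) and evaluated once
on the untouched 20% test split. Whether the two phases alternate or
run once is left open by the modelled procedure; the package runs a
single pass with an optional `outer_repeats`. A 2-fold
cross-validation mode (train on one stratified half, test on the
other, average) is available.

## 6. Metrics

One-vs-rest per class: precision TP/(TP+FP), sensitivity = recall
TP/(TP+FN), specificity TN/(TN+FP), F = 2PR/(P+R), all with 0/0 → 0;
macro (unweighted) averages by default, micro pooling behind a flag,
accuracy = trace/total either way. Reported sensitivity and recall are
the same macro quantity under this definition and are printed under
both names; sources that report them as different numbers without
defining either are not emulated. Per-class values ship alongside the
averages.

## 7. The synthetic world

The generator emulates a 4-class chest-CT dataset at desk scale: a
low-frequency background field in [40, 180] (bilinear upsampling of a
random 8×8 grid) plus class-specific bright rotated Gaussian ellipses —
25 medium blobs (adenocarcinoma-like), 4 very large blobs (large-cell),
none (normal), 80 tiny blobs (squamous-like), amplitudes 100–120 —
followed by 2% salt-and-pepper corruption. The parameters were chosen
once so the classes are *strongly separable* by the 14 global texture
features (a nearest-centroid probe on held-out phantoms reaches
≥ 0.8 by test assertion, ~0.95 in practice): the phantoms exist to
exercise the computation, and a pipeline defect should show up as an
accuracy drop, not disappear into irreducible class overlap.

What the phantoms do **not** emulate: lesion morphology and margins,
Hounsfield calibration, anatomy, scanner noise spectra, inter-slice
context. A green end-to-end test therefore establishes that the
pipeline's stages compose correctly and that the search finds genomes
that classify separable texture classes — it says nothing about
radiological performance on real CT data.

## 8. Numerical and degenerate-input conventions

* Equalization uses `floor` in the rank map; outputs are rounded after
  bilinear blending and clamped to [0, 255].
* Correlation of a zero-variance GLCM is 1; entropy uses 0·log 0 = 0.
* Constant images: skewness = kurtosis = 0.
* Elite ties keep the incumbent; label argmax ties take the lowest
  class index.
* Stratified splits round the per-class training count; every derived
  seed is a small fixed offset from the master seed (all < 2³¹).
* Positions are clipped (not reflected or resampled) at the box.

## 9. Known limitations

* The optional 2-D image mode is pure R and desk-scale only.
* SGD with a fixed learning rate can diverge for adversarial settings;
  this is reported (or scored as worst fitness), not repaired.
* Phase-2's 10-remora budget at 10 iterations samples a tiny fraction
  of the 8-dim genome space; the search reliably improves on the
  all-minimum baseline but is not claimed to find global optima except
  on the small certified grids used in the tests.
* Image I/O is plain-text PGM; PNG/JPEG/DICOM readers would be plug-in
  replacements but are deliberately not dependencies here.
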