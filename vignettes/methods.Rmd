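---
title: "Segmenting brain regions with a dual-pathway patch CNN and tracked localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting brain regions with a dual-pathway patch CNN and tracked localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dualpathseg)
```

## The problem

In whole-brain micro-optical imaging at roughly 10 µm isotropic resolution,
anatomical regions are aggregates of discrete cell bodies: their boundaries
are texture transitions, not intensity edges. Segmenting a region in 3D
therefore needs three kinds of information at once — the *local* texture
around a pixel, the *contextual* appearance of its neighbourhood, and the
*global* position of the region in the brain. `dualpathseg` implements a
segmentation framework built on that decomposition:

1. a **dual-pathway convolutional network** classifies each pixel from two
   co-centred patches of different physical extent (local + contextual);
2. **initial localization** registers an average-intensity atlas to the
   subject volume, maps the atlas region label across, and dilates the
   middle slice into a permissive search mask (Mask-init);
3. **tracking localization** propagates slice by slice: each slice's
   segmentation, dilated, becomes the search mask (Mask-track) for its
   neighbour, exploiting the slow slice-to-slice change of region outlines
   at high axial sampling.

Everything is exercised end-to-end on synthetic phantoms whose statistical
structure matches what the method assumes, so each stage's guarantees can
be tested against known ground truth.

## The classifier

A training sample is a pair of square patches centred on the same pixel:
51 × 51 px for local texture and 77 × 77 px for context, the label being
the ground-truth class of the centre pixel. Each patch feeds one of two
structurally identical pathways:

    [5×5 conv, stride 1 → ReLU → LRN → 3×3 max-pool, stride 2] × 2
    → 5×5 conv → ReLU

All convolutions are valid (unpadded) and pooling uses floor arithmetic,
giving the spatial trace 51 → 47 → 23 → 19 → 9 → 5. With channel
progression 32 → 48 → 64 per pathway, the two outputs concatenate to
**128 feature maps of 5 × 5**. A cascade 5 × 5 convolution turns these
into **512 maps of 1 × 1**. Both the concatenated maps and the cascade
output are tapped by fully connected layers of width 256, joined, passed
through a further 256-wide layer with ReLU and dropout (p = 0.5), and
classified by a softmax with multinomial logistic loss,

$$\ell(y, z) = \log\textstyle\sum_j e^{z_j} - z_y = -\log \sigma_y(z),$$

evaluated with a max-shift for stability. The 77 px patch is bilinearly
resampled to 51 px before entering its pathway: equal spatial outputs are
the only way the two pathways can concatenate into 128 maps of a common
5 × 5 extent, and resampling (rather than cropping) preserves the full
contextual field of view.

Several architecture constants are design choices of this package: the
intermediate channel counts (32, 48), the fully connected widths, the
dropout rate, and the LRN constants (size 5, α = 1e−4, β = 0.75, k = 1)
follow common practice for networks of this family. The terminal
per-pathway width (64), both patch sizes, and the 128/512 map counts are
fixed by the architecture's published geometry.

Training uses mini-batch SGD: batch 200, learning rate 0.01 with a ×0.1
step decay every 10,000 iterations, momentum 0.9, weight decay 5e−4,
capped at 100 epochs or 50,000 iterations. Desk-scale runs keep this
schedule but feed ≤ 5,000 patches for ≤ 4 epochs — enough for the
separable phantom textures (validation accuracy above 0.95 in the test
suite). The network is implemented in single-precision C++ (im2col +
GEMM); weights, shuffling and dropout are all seeded, so training is
bit-reproducible.

## Sample extraction and balance

Candidates are taken on a stride-3 grid (the stride is a package default;
"sampling at intervals" removes near-duplicate patches). Negatives split
into class A (small patch contains no region pixel) and class B (it
contains some). With N1, N2, N3 the class-A, class-B and positive counts,
the screening keeps

$$0.1\,N_1 + 3x\,N_2 = 3\,N_3,$$

i.e. a seeded 10% subsample of class A, a solved fraction *x* of class B,
and all positives; class-B negatives and positives are each tripled by
intensity augmentation (×1, ×1.2, ×0.8, clipped to the storage range),
class-A negatives are not. We read *x* as the **retained** fraction — the
balance equation counts surviving samples, so its left side must be the
retained totals; *x* is clamped to [0, 1] with a warning when the candidate
mix cannot balance. Patches crossing the image border are completed by
reflection padding, which preserves local texture statistics where zero
padding would fabricate an edge. The train/validation split is 80/20,
stratified by class.

## Initial localization

The atlas (average-intensity volume + label volume) is registered to the
subject with a three-level multi-resolution pyramid (×4, ×2, ×1). Each
level runs:

* an **affine stage** maximizing 32-bin joint-histogram mutual
  information over translation, rotation and log-scale. The optimizer is
  derivative-free (Nelder–Mead), seeded at the coarsest level by a small
  translation scan (±6 coarse voxels); MI's histogram gradient is noisy
  enough that a simplex search is more robust than explicit ascent at
  these problem sizes.
* a **symmetric nonlinear stage**: demons-style updates computed in both
  directions (atlas→subject and subject→atlas), each step smoothed with a
  fluid Gaussian (σ = 1) and the accumulated fields with a diffusion
  Gaussian (σ = 2), then symmetrised by averaging each field with the
  inverse of its opposite. This honours the two-direction structure of
  symmetric diffeomorphic energies while staying tractable; the exact
  optimizer of the published symmetric normalization method is not
  reproduced. A level whose nonlinear stage fails to raise MI is
  reverted, making MI non-decreasing per level; a field with > 1%
  non-positive Jacobians is re-smoothed.

The forward/inverse fields satisfy a composition residual below 0.5
voxels (checked by `validate_transform()`). The region label is mapped by
nearest-neighbour resampling; the **middle slice** of the mapped region's
nonzero range (lower median on ties) is dilated by a **50 px disk** into
Mask-init. Registration does not need to be exact: the dilation absorbs
residual error, and the package's guarantees are phrased accordingly —
mask *recall* of the true region must be ≈ 1, while mask precision
("redundancy") may be low.

## Tracking localization and interval prediction

Prediction inside a mask visits only pixels on a stride-2 grid —
one-quarter of the mask, a 75% computation saving — and fills unvisited
mask pixels from their nearest predicted neighbour (multi-source BFS;
the fill rule is a package choice, justified by the connectedness of
region masks). Probabilities binarize at 0.5 with ties to background.
Each slice's raw (pre-postprocessing) result, dilated by a **20 px
disk**, localizes the adjacent slice; propagation runs from the starting
slice toward both volume ends and stops in a direction when predicted
foreground falls below `min_area` (default 20 px, a package choice; the
tracking naturally ends where the region disappears). If per-slice
boundary drift plus per-slice segmentation error stay below the track
radius, the true region is contained in every Mask-track — recall 1 —
which the test suite asserts on phantoms.

Postprocessing iterates per-slice hole filling, removal of 3D connected
components below 20 voxels (26-connectivity), and 3D Gaussian smoothing
(σ = 1) re-thresholded at 0.5, to a fixed point (the smoothing acts like
a discrete curvature flow that settles within a few tens of passes).
Running to the fixed point makes the operation exactly idempotent, at the
price of a slight extra boundary erosion relative to a single pass.

## The phantom generator

`make_phantom()` emulates the statistics the method relies on, not the
appearance of real data:

* a superellipse region (exponent 2.5) whose centre and radii follow a
  clamped random walk with per-slice boundary drift ≤ `d_max` (default
  10 px) — the slow slice-to-slice change that tracking assumes;
* "cell body" texture: Gaussian blobs (radius 4 px, σ = 2) scattered by
  Poisson processes at 8 / 1,000 px² inside and 1 / 1,000 px² outside,
  over a background pedestal, with an in-region pedestal solving for a
  region/background mean-intensity ratio of 3 (8-bit storage);
* `make_atlas_pair()` deforms the subject by a seeded sinusoidal
  displacement field — wavelength ≥ 16× the amplitude, axial component
  tapered at the volume ends and in-plane components tapered at the
  borders so the warp is fold-free (positive Jacobian, verified
  numerically) and never displaces content out of the domain; the
  ground-truth transform is returned with forward and inverse fields;
* `add_noise()` reproduces two acquisition artefacts: multiplicative
  illumination stripes (default period 40 px) and radial vignetting.

The defaults (100 slices of 200 × 300 px, 10 µm spacing) are the package's
standing study conditions; tests and the acceptance script state smaller
shapes where they use them. What phantoms do *not* model: vasculature and
fibre structures, anisotropic point-spread blur, intensity inhomogeneity
between specimens, and regions with multiple disconnected components per
slice. Passing on phantoms therefore demonstrates the machinery —
balance, containment, propagation, registration recovery — not
performance on real tissue.

## Numerical choices and degenerate inputs

* Coordinates are 0-based (slice, row, col) in C++ and 1-based in R;
  the slice axis is always axis 1; spacing is carried in micrometres.
* Dice(∅, ∅) = 1; precision/recall with empty denominators are `NA` and
  surfaced, never silently dropped.
* `solve_balance()` with no class-B negatives errors unless the set is
  already balanced; screening still applies the 10% rule and warns.
* Thresholding ties (probability exactly 0.5) go to background.
* Dilation uses the exact digital disk (pixels within Euclidean distance
  r); radius 0 is the identity.
* The displacement-field inverse is computed by fixed-point iteration;
  transforms are validated for composition residual < 0.5 vox and ≤ 1%
  non-positive Jacobians.
* Patch extraction reflects indices at borders (edge not duplicated).
* All stochastic operations take explicit seeds and restore the caller's
  RNG state.

## Desk-scale problem sizes

The test suite and the acceptance script run everything at sizes a single
CPU handles comfortably, as the package's own validation scale: training
phantoms of 30 × 160 × 160 voxels, ≤ 5,000 balanced patches, 4 epochs;
registration phantoms up to 40 × 200 × 300; a 24-slice held-out volume
for the end-to-end run. The pipeline's accuracy targets (localization
recall ≈ 1, end-to-end volume Dice ≥ 0.9) are met at these sizes; the
architecture and all rule constants are identical to the full-scale
configuration.

## Known limitations

* The registration's nonlinear stage is a demons-style approximation of
  symmetric diffeomorphic matching, adequate for smooth phantom warps;
  strongly non-smooth or large-rotation misalignments would need a more
  powerful optimizer.
* Single-region tracking only; regions that split into several connected
  components along the axis are followed only through components reached
  from the starting slice's mask.
* The CNN is trained per region; no multi-region model is provided.
* Phantom realism is deliberately limited (see above), so real-data
  performance claims are out of scope for this package's tests.
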