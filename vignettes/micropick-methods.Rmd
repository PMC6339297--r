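---
title: "micropick: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{micropick: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropick)
```

`micropick` turns per-pixel particle-probability maps of cryo-EM
micrographs into particle coordinates, generates segmentation training
labels from a reconstruction, and ships the simulator and metrics needed
to test both. This vignette explains the procedures, the parameters that
matter, and the design decisions taken where the underlying method leaves
choices open.

## The picking model

The input is a probability density map `V`: a raster the size of the
micrograph whose value at a pixel is the likelihood that the pixel lies
on a particle rather than background. Picking proceeds in five fixed
stages.

**1. Candidate scoring.** Every pixel is treated as a candidate particle
center and scored by correlating the map with a normalized Gaussian
lattice `W` of side `s` (the particle size):
`score(m, n) = sum_{x,y} W(x, y) V(m+x, n+y)`. The Gaussian gives central
pixels more influence, which keeps the score of a particle from being
inflated by a close neighbor. `sigma` defaults to `s/4`, which puts
essentially all (>95%) of the kernel mass inside the particle box; it is
configurable because sharper kernels localize better on small or
crowded particles. The lattice spans `-s/2 ... s/2`, so its side is `s`
for odd `s` and `s + 1` for even `s`: a symmetric lattice with a unique
central maximum does not exist on an even grid, and the odd lattice is
what the scoring sum's index range describes. Outside the map the
probability is taken as 0 (zero padding), which deliberately depresses
scores within `s/2` of the edge — edge particles are cut off and better
left unpicked.

**2. Grid initialization.** The map is tiled into cells of side
`g = floor(s/2)` (ceiling division, so the last row/column of cells may
be partial) and one candidate is placed per cell at the cell maximum.
This bounds the number of candidates by `ceil(H/g) * ceil(W/g)` — 1681
for a 4096×4096 map at `g = 100` versus 16.8 million pixel-wise — and,
because two survivors of the later separation filter are at least `s/2`
apart, bounds the per-axis overlap of accepted boxes by `s/2`, i.e.
`s^2/4` of shared area for axis-aligned offsets.

**3. Local-maximum ascent.** Each candidate repeatedly jumps to the
maximum of the score map within a square window of half-side
`search_radius` about its position until the position is a fixed point or
`max_iters` (default 100) is reached. The window defaults to the grid
side `g` so a candidate can always escape its starting cell; larger
windows converge in fewer, more expensive jumps. Because each jump is to
a window maximum that includes the current pixel, scores are
non-decreasing, and termination is guaranteed by the iteration cap (in
practice the median is a handful of iterations). Candidates are mutually
independent — the loop parallelizes trivially, though this implementation
is serial.

**4. Deduplication.** Candidates from different cells frequently converge
to the same local maximum. Greedy non-maximum suppression sorts by
descending score and accepts a candidate only if it is at least
`min_separation` (default `s/2`) from every earlier acceptance.

**5. Filtering.** Candidates below `score_threshold` (default 0.6) are
dropped and at most `max_picks` (default 500) survivors are kept, best
first. In the full segmentation-plus-classification design this is where
a trained classifier re-scores candidates to remove false positives such
as ice contamination; `micropick` exposes exactly that slot as the
`scorer` function hook (re-score, re-threshold) so a trained model can be
plugged in without changing the pipeline. With no hook, the threshold
applies to the normalized kernel scores themselves; whether such a
threshold is comparable to a classifier-probability threshold is a
judgment the user should make per dataset — the scales are different
quantities that happen to share [0, 1].

**Determinism.** Every tie anywhere in the pipeline (cell argmax, window
argmax, equal NMS scores) is broken by the lowest row-major linear index
(`y * W + x`), making the whole pipeline a pure function of its inputs.

## Label generation

Training a segmentation network requires per-pixel labels nobody can
annotate by hand at cryo-EM noise levels. The automated route implemented
here exploits a completed refinement: its reconstruction, and each
particle's refined orientation and translation, are a high-SNR
description of what each particle looks like. Per particle:

1. **Reproject** the volume at the particle's Euler angles. Angles are
   interpreted as intrinsic ZYZ `(rot, tilt, psi)` in degrees, the
   convention of the mainstream refinement packages whose outputs serve
   as input here. Rotation uses trilinear interpolation about the volume
   center followed by a z-sum; at the identity rotation the sampling grid
   coincides with the voxel grid and the projection equals the direct
   axis sum exactly.
2. **Translate** the reprojection by `(+dx, +dy)` (bilinear for
   fractional shifts, zero-filled) to align it with the particle as it
   was extracted. STAR origin conventions differ in sign between tool
   versions, so the sign is configurable (`translation_sign = -1`).
3. **Binarize** with Otsu's threshold computed on the tile's own
   histogram. The method prescribes "binarization" without a rule; Otsu
   is parameter-free, per-tile adaptive, and testable against an
   exhaustive-threshold oracle. A constant tile yields an all-zero mask
   (no foreground). Binarization runs after the translation by default;
   the order is configurable (`binarize_first`) since either reading is
   defensible and they differ only by interpolation effects.
4. **Composite** tiles into the micrograph-sized label map at the
   particle centers, combining overlaps by logical OR (labels are a class
   mask, not instances) and clipping at the edges.

`generate_label_dataset()` then cuts aligned (image, label) windows at
seeded uniform offsets — any window size with zero-padded edges, rather
than a fixed tiling.

One caveat inherited from the approach itself: it assumes the coordinate
table is exhaustive, i.e. unlabeled regions truly contain no particles.
Nothing in the code can verify that for real data.

## The simulator

The generator exists so every stage is testable against known ground
truth without downloads. Its defaults are the package's standard test
condition: 25 particles, box size `s = 32` px (particle radius 12), on a
512×512 micrograph, pairwise separation at least `2s = 64` px, additive
white Gaussian noise at 0 dB, mask blur sigma 2 px, one RNG stream drawn
in a documented order (volume, placements, noise) so a seed fixes every
artifact bitwise.

* **Volumes** are unions of 1–5 soft-edged spheres/ellipsoids (edge width
  1.5 voxels) inside a ball of the configured radius — blob-like particles
  with orientation-dependent projections, not any specific molecule.
* **Noise** is white Gaussian scaled in closed form so the measured
  energy-ratio SNR hits the target exactly; the SNR helper reports both
  the dB scale `10*log10(sum(f_hat^2)/sum((f-f_hat)^2))` and the linear
  ratio, because "SNR 0.01" in the particle-picking literature usually
  means the linear power ratio (−20 dB) — both scales are first-class to
  avoid ambiguity.
* **Probability maps** are the blurred, [0, 1]-rescaled ground-truth
  masks: an idealized, noise-free stand-in for a segmentation network's
  output.

What this does **not** emulate: contrast transfer, dose and ice physics,
structured background, carbon edges, particle overlap and aggregation,
and — most importantly — the error modes of a real segmentation network
(false blobs, merged particles, intensity that is not a calibrated
probability). Passing tests on simulated maps therefore validate the
*coordinate extraction machinery*, not end-to-end picking performance on
real micrographs.

## Numerical choices and degenerate inputs

* Coordinates are 0-based particle centers, `x` = column, `y` = row,
  origin top-left; EMAN `.box` corners convert via
  `center = corner + floor(box/2)` at the I/O boundary only.
* MRC2014 I/O is mode-2 float32, little endian, `(z, y, x)` axis order
  in memory with x fastest on disk; pixel size is `CELLA/MX`. Round
  trips are bitwise stable after the initial float32 quantization.
* Score-map values are clamped to [0, 1] when the input lies in [0, 1]
  (FFT filtering can overshoot by machine epsilon).
* `iou(empty, empty) = 1`: perfect agreement on absence; a 0/0 would
  otherwise poison means.
* Zero-denominator precision/recall raises an error rather than
  reporting a silent 0.
* Cross-channel response normalization clips its channel window at the
  boundaries (no wrap); convolutions are "valid" (no padding), matching
  the index ranges that define them.
* Local response normalization defaults `a = 1e-4`, `b = 0.75` follow
  the customary layer parameterization.

## Known limitations

* Otsu binarization trims the thin-chord rim of a smooth projection: for
  a uniform sphere the mask is a disc about 10% smaller in radius than
  the sphere. Labels and simulator ground truth binarize identically, so
  the discrepancy cancels in fidelity comparisons, but absolute mask
  areas are conservative.
* The `s^2/4` overlap bound from `min_separation = s/2` is exact for
  axis-aligned offsets; a diagonal offset at exactly `s/2` can overlap
  slightly more. With the default separation of well-formed inputs
  (particles are not closer than `s/2` in practice) the bound holds on
  every pipeline output we assert it on.
* Greedy score-ordered matching can in principle fall short of the
  optimal assignment TP count; on randomized small instances it matches
  the exhaustive optimum, and it is the deterministic, explainable choice.
* The picker is O(map) in memory and serial; 4096×4096 maps are fine,
  but the implementation makes no attempt at tiling or parallelism.

## Problem sizes used by the test suite

Unit tests use rasters up to 32×32 and volumes up to 24³ against
brute-force oracles; pipeline and acceptance properties run at the
default 512×512/25-particle condition plus one 4096×4096 grid-counting
check. The full suite completes in well under a minute on one CPU.
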