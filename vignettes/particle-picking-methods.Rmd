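---
title: "Methods: transformer-based particle picking in cryo-ET tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transformer-based particle picking in cryo-ET tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cryo-electron tomography reconstructs the 3D density of vitrified cellular
samples from a tilt series of micrographs. Locating (and classifying) the
macromolecular particles inside a tomogram — *particle picking* — is the
bottleneck between reconstruction and subtomogram averaging. Tomograms are
very large (hundreds of voxels per axis), extremely noisy (power SNR commonly
below 0.1), and anisotropic due to the missing wedge of unsampled Fourier
space. `tomopick` implements a complete picking pipeline: standardization,
volumetric feature extraction, windowed dense segmentation with a 3D
shifted-window transformer U-Net, and post-processing to particle
coordinates with one-to-one matched evaluation.

## Standardization

Input volumes are MRC files. All spatial metadata (voxel size, origin, axis
permutation of the header) are carried through the pipeline; data are held in
a canonical `[x, y, z]` array and the header axis order is applied only at
the I/O boundary, so a read/write cycle is a fixed point for all six axis
permutations.

* **Resampling.** `resample_isotropic()` brings heterogeneous voxel spacings
  to a common grid (trilinear interpolation in physical coordinates, target
  1 Å by convention). Sampling positions outside the source grid clamp to the
  edge, so borders are extrapolated flat rather than zero-filled.
* **Intensity normalization.** `percentile_normalize()` maps `V` to
  `clip(V / p95(V), 0, 1)`. By default the 95th percentile is taken over all
  finite voxels; `nonzero_only = TRUE` restricts it to non-zero voxels, which
  matters for reconstructions with zero padding slabs and for noise-free
  synthetic volumes whose background is exactly zero. This is idempotent:
  after one pass the 95th percentile is 1, so a second pass is a no-op.
* **Coordinate alignment.** Some simulated benchmarks centre a thinner
  ground-truth model inside the reconstruction, so annotation z = 0 sits at a
  positive reconstruction slice; `align_coordinates()` applies the per-dataset
  z-offset (+156 and +166 voxels for the two standard simulated sets) to
  coordinate tables only — masks are assumed co-registered. Coordinates are
  0-based floating-point voxels throughout; anyone comparing against
  external annotation files should check that convention first.
* **Label construction.** `remap_class_mask()` folds per-dataset class ids
  into a unified space `{0..K}` via an explicit mapping table; vesicle and
  membrane ids are excluded to background because they are not macromolecule
  particles. The remap is a pure per-voxel relabeling: the occupancy (the
  actual segmented shape of each instance) is never replaced by synthetic
  spheres, so supervision reflects true particle geometry.
  `binarize_mask()` collapses all particle classes to one foreground class.

## Feature extraction

Detection at low SNR benefits from explicit multi-scale cues. Three feature
volumes are computed **on the full normalized tomogram** (so window borders
see true context) and stacked with the density into a fixed-order 4-channel
input `[normalized, gradient magnitude, combined top-hat, DoG-max]`:

* **DoG blobness.** For scales `s in {1,2,4,8}` voxels the response is
  `G(ks) - G(s)` with `k = sqrt(2)` by default (`k` is configurable; `k = 2`
  selects a coarser band-pass). Responses are optionally multiplied by `s^2`
  (scale normalization, on by default) and the *signed* response of the scale
  with maximum absolute magnitude is kept per voxel, then clipped to the
  [0.01, 99.99] percentile interval.
* **Sobel gradient magnitude.** Derivative stencil `(-1,0,1)` with `(1,2,1)`
  smoothing on the orthogonal axes, normalized by 1/32 so that a unit-slope
  ramp responds exactly 1 per voxel; components are divided by the voxel size
  so gradients are per Ångström; replicate boundaries.
* **Top-hat contrast.** White (`I - open(I)`) and black (`close(I) - I`)
  top-hats with discrete Euclidean ball elements of radius `s`, weighted by
  `s^(1/2)`, aggregated across scales by voxel-wise maximum; the combined map
  is the maximum of the two polarities, percentile-clipped like the DoG.

Numerical conventions worth noting: Gaussian kernels are truncated at 4
sigma and renormalized; all boundary handling is replicate (clamp-to-edge);
percentile clipping uses R's default (type 7) quantiles; grey morphology
ignores out-of-bounds neighbours so constants are preserved exactly.

## Gridding

`split_volume()` tiles a volume with **disjoint** 48-voxel cores and extracts
a 64-voxel window around each core (8 voxels of context per face), zero-
padding where a window leaves the volume. The disjoint-core/overlapping-
window reading is the only one under which stitching is write-once and exact:
`stitch()` writes back only the in-volume core region of every window, making
`stitch(split(v)) == v` an identity for arbitrary volumes, which the tests
assert across shapes including non-divisible and anisotropic ones. For
training only, `filter_nonzero()` drops input/mask window pairs whose mask
window is empty; inference always covers the full volume. Window sizes must
be divisible by 16 so they survive the network's four halvings (validated at
configuration time).

## The segmentation network

A U-Net built from 3D shifted-window transformer stages:

* **Stem and widths.** A 1x1x1 linear embedding maps the 4 input channels to
  `hidden_dim / 2` at full resolution; each of the four encoder stages then
  applies a patch-merge (non-overlapping 2x2x2 blocks flattened to tokens of
  length `8C` and projected, then layer-normalized) followed by an even
  number of transformer blocks. Widths double per stage:
  `hidden_dim * 2^(stage-1)`, i.e. 32/64/128/256 at the default
  `hidden_dim = 32`.
* **Attention geometry.** Blocks alternate regular and cyclically shifted
  (by half a window) window attention with windows of 2x2x2 tokens. Q/K/V
  are projected to `heads * head_dim` (default head counts 3/6/12/24 with
  `head_dim = 32`), decoupled from the stage width, and the attended output
  is projected back to the stage width; this keeps the published head
  schedule compatible with the doubling widths. A learnable relative-position
  bias table with `(2w-1)^3` entries per head is added to the logits. Shifted
  blocks add a `-1e4` mask to token pairs that share a window only through
  wrap-around at the volume boundary, so masked pairs receive attention
  weight below 1e-6.
* **Blocks.** Pre-norm residual structure: `x + Attn(LN(x))` then
  `x + MLP(LN(x))` with a GELU MLP expanding channels 4x; dropout (training
  only) sits in the MLP path.
* **Decoder.** Patch-expand modules mirror the merges (linear projection to
  `8 C_out` then spatial rearrangement and layer norm), additive skip fusion
  `LN(F_dec + F_enc)` with the same-resolution encoder output, then the
  mirrored block stack. A final expansion restores full resolution at
  `hidden_dim / 2` channels, followed by layer norm, GELU and a 1x1x1 linear
  head to K class logits.
* **Training.** Class-weighted cross-entropy, mean-reduced over voxels with
  weights normalized to mean 1 (inverse-frequency weights
  `w_k ~ N / (K * max(N_k, 1))` derived from corpus voxel counts by
  default), Adam, and global-norm gradient clipping
  (`norm <- min(norm, tau)`). One seed fixes initialization (truncated
  normal, sd 0.02), shuffling and dropout, so runs are bit-reproducible.
  Per-epoch checkpoints carry model state, optimizer state, loss history,
  best validation record and a full configuration snapshot.
* **Inference.** Softmax posteriors, argmax, and a global confidence
  threshold `tau` (default 0.5): voxels whose maximum posterior falls below
  `tau` become background. In binary mode the particle posterior is
  thresholded directly.

The whole network, including backpropagation, is implemented in base R
matrix operations; gradients of every layer and of the assembled network are
verified against central finite differences in the test suite, and windowed
attention is verified against a dense brute-force evaluation.

## Post-processing and evaluation

`connected_components()` labels each predicted class with 18-connectivity
(6 face + 12 edge neighbours; corners excluded) — verified against a
flood-fill oracle for all three standard connectivities. Components smaller
than `min_size` (default 5 voxels, inclusive boundary) are removed and each
survivor contributes its unweighted voxel centroid. Evaluation uses optimal
one-to-one assignment (Hungarian algorithm, implemented in compiled code and
verified against exhaustive enumeration) on the Euclidean distance matrix
with entries above `d_max = 5` voxels invalidated (set to `1e6 * d_max`);
assignments landing on invalid entries are discarded. `TP` is the number of
matched pairs within the cutoff, `FP = N_pred - TP`, `FN = N_gt - TP`;
precision, recall, F1 and miss rate follow, with zero-denominator ratios
reported as `NA` rather than 0, and `AD` is the mean matched distance.
Matching is pooled for binary evaluation and within-class for multiclass
evaluation. Multiple hits cannot occur under one-to-one assignment, so that
count is structurally zero here. Distances are in voxel units (the cutoff is
stated in voxels); with anisotropic voxels a physical-unit cutoff would need
rescaled coordinates.

## The synthetic-data generator

`simulate_tomogram()` plants solid spheres (default) or Gaussian blobs of
per-class radius and amplitude at rejection-sampled centres with a minimum
pairwise distance, adds i.i.d. Gaussian noise, and returns the density, the
exact occupancy mask (voxels within the radius, labelled by class) and the
centre table. Defaults emulate the study conditions: a 64-voxel cube with
two size classes (radius 3 and 5 voxels, ten particles total), amplitude 1,
noise sigma 1 — power SNR about 1, an easy regime for smoke tests; sigma of
roughly 3.2 gives the power-SNR 0.1 regime typical of real data. The
minimum centre distance defaults to `2 * max(radius) + 2` so instances do
not overlap. An optional missing-wedge filter zeroes Fourier coefficients
beyond the tilt half-angle (symmetrically in k, so the output stays real),
reproducing the characteristic z-elongation.

What the generator does **not** model: structured cellular background,
membranes and filaments, CTF and dose effects, reconstruction artifacts
other than the wedge, and realistic particle shape variety. Passing tests on
simulated data therefore demonstrate that the machinery is correct and that
the network can learn and localize under calibrated noise — not that the
default hyperparameters transfer to any particular real dataset.

## Reduced-scale behavioural check

The test suite and the acceptance script train a reduced network —
`hidden_dim` 16, depths (2,2,2,2), heads (1,2,4,8), `head_dim` 16, dropout 0
— on eight simulated 32-voxel volumes (one window each, core 32 / pad 0, about
six thousand foreground voxels in total), each containing three particles
(two of radius 3, one of radius 5) at noise sigma 1, and evaluates detection
on four held-out volumes at the default confidence threshold 0.5 and cutoff
5 voxels. The component size filter for this run follows the usual
practitioner's rule — half the smallest planted particle's discrete volume
(radius 3 spans 123 voxels, so 60) — rather than the package-wide default of
5 voxels, which is meant for sub-nanometre-scale targets and would pass tiny
noise blobs for particles this large. Sixty epochs of Adam at learning rate 3e-3
with batch size 2 and clip 1 converge in a few CPU-minutes; these problem
sizes were chosen so the whole suite runs comfortably on one core. The
particle density (about three particles per 32-voxel cube) matches the
default generator density per unit volume; packing many large particles into
so small a box would instead probe instance *separation*, which
connected-component post-processing intentionally does not attempt to solve
(adjoining same-class particles merge into one component — a known
limitation shared by this entire family of segmentation-based pickers).

## Design choices on genuinely open points

* **DoG sigma ratio.** Written ambiguously in the source material; the
  conventional `sqrt(2)` is the default and `k` is a visible parameter.
* **Signed vs absolute DoG.** The signed value at the argmax-|response|
  scale is kept, matching the printed selection rule.
* **"Informative" voxels for the percentile.** All finite voxels by
  default, non-zero-only behind a flag; deterministic and mask-free.
* **Merge width schedule.** Doubling per stage from `hidden_dim`, with the
  half-width stem making all four merges uniform doublings.
* **Attention inner width.** `heads * head_dim` decoupled from the stage
  width (see above) — the only reading that makes 3 heads of dimension 32
  compatible with a 32-channel stage.
* **Skip norm.** Layer normalization over channels, the same normalization
  used everywhere else in the network.
* **Class weights.** Corpus-level by default (stable for small corpora);
  per-batch weighting can be emulated by passing explicit weights.
* **Size-filter boundary.** Inclusive (`size >= min_size` survives),
  default 5 voxels.
* **Invalid-cost constant.** `1e6 * d_max`, large enough that invalid
  assignments are never preferred yet finite for the solver.

## Known limitations

Training in base R is practical at reduced scale (minutes per run) but not
at the full 64-voxel, width-32 configuration with hundreds of windows —
that remains the domain of GPU frameworks; the architecture, losses and
inference here are nonetheless the complete method, verified at small scale.
Touching particles of the same class merge during component extraction.
The simulator's noise model is white Gaussian; correlated noise from
weighted back-projection is not emulated. Evaluation assumes a single
ground-truth point per instance.
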