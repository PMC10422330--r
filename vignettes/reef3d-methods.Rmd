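---
title: "Methods: multi-modal reef segmentation and 3D structural change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal reef segmentation and 3D structural change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`reef3d` implements a pipeline for fine-grained monitoring of coral-reef
habitats from photogrammetric survey products. Its inputs are the standard
outputs of an underwater photogrammetry workflow: a co-registered
orthomosaic (RGB) and digital surface model (DSM) at millimeter grid
resolution, plus dense point clouds and triangle meshes in the same metric
frame. The pipeline has two halves:

1. **Multi-modal semantic segmentation.** A compact encoder-decoder
   network labels each cell as background, live coral, or dead coral from
   the RGB channels *and* the height channel. Dead coral skeletons are
   often nearly indistinguishable from pale substrate in color, but retain
   intact branching relief; the height channel carries exactly that cue.
2. **Class-stratified 3D structural change.** DSM differencing, multi-scale
   vector ruggedness (VRM) and multi-scale point-cloud roughness quantify
   growth, mortality and structural complexity, stratified by the predicted
   classes and projectable onto 3D meshes for inspection.

Because no public benchmark dataset exists for this task at this
resolution, the package carries a first-class synthetic scene generator
(`generate_scene()`, `evolve_scene()`) that produces two-epoch reef scenes
with *known* growth, mortality and removal, so every stage of the pipeline
is testable end-to-end against ground truth.

# The segmentation network

## Architecture

`mmcs_config()` describes an encoder-decoder in the DeepLabv3+ mold:

* a convolutional backbone over the 4-channel RGB+DSM input (3-channel when
  `use_dsm = FALSE`), with strided stages to 1/4 resolution and a dilated
  final stage;
* atrous spatial pyramid pooling (ASPP): parallel 1x1 and dilated 3x3
  branches whose concatenation is projected down, capturing context at
  several effective scales;
* a decoder that upsamples the ASPP output, fuses a reduced low-level
  feature map, and refines through depthwise-separable 3x3 convolutions
  before the classifier head.

Two presets are provided. `tiny` (4 stages, at most 32 channels, ASPP rates
2 and 4) is designed to train on a single CPU core in minutes and is the
configuration exercised by the test suite; `full` is a wider and deeper
variant (ASPP rates 6/12/18, residual units per stage) with the same code
path. The backbone is deliberately configurable rather than tied to a
published classification network: the architecture contribution under test
is the input modality, the shape-aware convolution and the loss, not the
backbone depth.

All layers are implemented in the package (im2col/col2im in C++, layer
forward/backward passes in R over BLAS matrix products) with hand-written
backpropagation. Correctness is guarded by two independent checks in the
test suite: a brute-force window oracle for the convolution variants, and a
finite-difference gradient check through the entire network.

## Shape-aware convolution

For each K x K input window `P` (per input channel), the layer splits

* a **base** component: the spatial mean of `P`, and
* a **shape** component: the residual `P - base`,

reweights them with learnable weights (`w_base`, one scalar per input
channel; `w_shape`, one weight per kernel position and channel), recombines
`P' = w_base * base + w_shape o shape`, and applies the ordinary
convolution kernel to `P'`. The intuition for a height channel: the base
carries absolute elevation, which is nearly meaningless for class identity,
while the shape component carries local relief, which is the discriminative
signal. Both weights initialize at 1, making the layer *exactly* a vanilla
convolution at the start of training (verified to 1e-5 in the tests);
because the recombination is linear in the unfolded window, the trained
weights fold into the kernel (`fold_shape_weights()`), so inference costs
nothing extra. Shape-aware layers replace the backbone convolutions only;
ASPP and the decoder keep plain and separable convolutions.

## Hybrid loss

Training minimizes

$$L = L_{CE} + \mu\, L_{IoU}, \qquad \mu = 0.4$$

where $L_{CE}$ is the mean pixel-wise cross entropy and $L_{IoU}$ is a soft
(differentiable) intersection-over-union loss: per class $c$,
$I_c = \sum_i p_{ic} y_{ic}$ and $U_c = \sum_i (p_{ic} + y_{ic} - p_{ic}
y_{ic})$ over non-ignored pixels, and $L_{IoU} = 1 - \mathrm{mean}_c\,
I_c/U_c$. Cross entropy provides smooth per-pixel gradients; the IoU term
scores whole regions and concentrates effort on getting foreground
footprints right. With $\mu = 0$ the loss reduces exactly to cross entropy
(this is how the ablation baselines are trained). The IoU average runs over
all classes including background by default; `iou_foreground_only`
restricts it to the coral classes.

## Normalization and optimization

Input normalization for a mixed RGB + height stack is a genuine design
choice; the package's choices are:

* RGB: divide by 255, then standardize per channel with statistics of the
  training patches (stored in the fitted model).
* DSM: subtract the *patch median*, divide by a fixed 0.05 m scale.
  Removing the patch median removes the arbitrary absolute depth while
  preserving relief amplitude across patches — precisely the quantity the
  shape component is meant to exploit. A fixed scale (rather than per-patch
  standard deviation) keeps flat sand patches flat instead of amplifying
  their noise.

Optimization is Adam at a peak learning rate of 1e-3 with cosine decay over
the requested epochs; gradients are averaged over minibatches, and all
randomness (initialization, shuffling, validation splits) flows from the
`seed` argument through R's RNG, making runs bit-reproducible on a given
platform. A divergent (non-finite) loss aborts with the offending epoch.

`mmcs_fit()` follows the classic R modelling idiom: it returns an
`"mmcs_net"` object with `print`, `summary`, `coef`, `plot` (training
curves) and `predict` (full-scene inference) methods. With a
`kfold_split()` it trains once per fold — each fold serving once as the
validation set — and reports per-fold histories plus averaged mPA/mIoU;
metrics are computed at patch level by default, with scene-level metrics
available by evaluating a stitched prediction against the scene labels.

# Tiling and stitching

Scenes are cut into `window x window` patches (default 448, a patch size
that balances context and memory at mm-resolution orthomosaics) at a
stride of half the window (default 224). Patch
counts per axis follow `floor((extent - window)/stride) + 1`. Patches whose
height channel is more than half nodata are dropped — the threshold is a
package choice where the protocol is silent, avoiding degenerate loss
terms. Augmentation applies identical geometric transforms to all
channels; rotations are restricted to multiples of 90 degrees so the height
channel and the categorical labels are never interpolated, and translations
are realized as jittered re-crops from the source rasters (up to half a
stride). At inference, overlapping patch probabilities are averaged before
the argmax, with ties broken toward the lower class id for determinism;
cells no patch covers are nodata.

# Terrain analysis

* **Slope/aspect** use Horn's 3x3 stencil, the convention of ArcGIS and
  the Benthic Terrain Modeler that reef rugosity studies rely on. Aspect is
  measured clockwise from grid north; flat cells get aspect 0, which is
  immaterial because their normals have `sin(slope) = 0`.
* **VRM** decomposes each cell's unit normal into
  `(sin s sin a, sin s cos a, cos s)`, sums normals over an odd
  `window x window` neighborhood into a resultant `R`, and reports
  `1 - |R|/n_cells`, so a flat or uniformly tilted surface scores exactly 0
  and maximal dispersion scores 1. Windows are **nodata-strict**: any
  nodata cell (including the one-cell stencil border) voids the output
  cell. This avoids biased resultant magnitudes; users with small holes
  should fill them beforehand. Box sums run over summed-area tables, which
  are exact for these magnitudes. The scale-dependence the field relies on
  (windows of 21/51/101 cells at 1 mm spanning polyp to colony scales) is
  exposed via `window_px`, and per-class stratification assigns each cell
  its own mask class.
* **DSM differencing** is pixel-wise subtraction reported in millimeters
  (`(t2 - t1) * 1000`); heights are meters internally, and the mm
  conversion happens only at this reporting boundary. Change distributions
  are summarized by median and quartiles — the skewed distributions of
  reef height change make the median the honest central tendency — and the
  conventional display truncation at +-50 mm applies to histograms and the
  diverging red-white-blue mesh coloring only, never to statistics.

# Point-cloud roughness

Roughness of a point is the perpendicular distance to the total
least-squares plane (centroid plus smallest-eigenvalue direction of the
neighbor covariance) fitted to the point's neighbors within a radius,
computed at several radii (20/50/100 mm by convention). Two documented
choices where tools differ:

* the query point is excluded from its own plane fit ("its neighbors");
  including it shrinks distances systematically;
* at least 3 non-collinear neighbors are required, otherwise the point gets
  nodata; neighbor counts are not capped.

The implementation hashes points into a uniform grid with cell size equal
to the radius, so neighborhoods are exact (the contract is exactness, not
a particular index structure); the test suite compares it against an
O(N^2) brute-force oracle. Roughness is invariant under rigid motions and
scales linearly with uniform scaling — both are property-tested.

# Mesh projection

`project_raster_to_mesh()` assigns raster values to mesh vertices by
vertical ray: labels by containing-cell lookup (categorical data is never
interpolated), scalars by bilinear interpolation. For height-field meshes
(one vertex per DSM cell, as `build_mesh()` produces) this projection is
exact; for photogrammetric meshes with overhangs it is an approximation,
which is the documented limitation of a 2.5D projection. Class colors
follow the field's display convention (dark pink live, light pink dead,
gray background); change scalars use the diverging red-white-blue map over
+-50 mm with clamping.

# The synthetic scene generator

`generate_scene()` emulates a fore-reef survey scene dominated by branching
coral colonies:

* a smooth substrate (superposed long-wavelength cosines) with optional
  gray rock outcrops and per-cell height noise (default sd 0.5 mm,
  matching the order of photogrammetric surface noise at mm grids);
* non-overlapping hemispherical colonies (rejection-sampled with a 4 mm
  separation, so the truth table corresponds exactly to connected label
  components), with fine ridge relief on the colony surface; dead colonies
  keep the ridge relief — a freshly dead skeleton is structurally intact;
* class-dependent base colors (live dark pink, dead pale pink, sand tan,
  rock gray) under a multiplicative linear illumination gradient (default
  amplitude 0.15, emulating the smooth illumination changes wave refraction
  leaves after radiometric correction) plus RGB noise.

`evolve_scene()` applies a prescribed `epoch_delta()`: uniform vertical
growth on surviving live colonies, mortality (relabeling with unchanged
DSM), and removal (reversion to substrate). Untouched cells are
bit-identical across epochs, which is what makes exact parameter-recovery
tests possible: the median height change over surviving live-colony cells
equals the prescribed growth exactly.

The generator deliberately does **not** emulate photorealistic water-column
optics, camera geometry, reconstruction artifacts (holes, doming,
registration error) or biological texture diversity. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that its
qualitative orderings hold under controlled conditions — not that the
reported accuracy transfers to real surveys.

## Study conditions used by the validation suite

Problem sizes were chosen once as CPU-scale study conditions:

* **Smoke benchmark**: 200 patches of 48 x 48 cells from eight 240 x 240
  scenes with strong color and height separation; tiny preset, 30 epochs,
  batch 8, seed 1; the validation mIoU must reach at least 0.7 (it reaches
  about 0.97).
* **Ablation direction**: scenes whose dead colonies are colored exactly
  like sand, so the RGB-only Model A cannot see them while the RGB+DSM
  Model B can; three seeds, five 192 x 192 scenes each (80 patches), 40
  epochs at batch 4 (the smaller batch gives the optimizer enough steps to
  discover the height cue at this data scale). The mean validation mIoU of
  Model B must be at least that of Model A: adding the height channel
  should never hurt when the missing class is encoded in relief.
* **Scale dependence**: on a 256 x 256 scene, the live-coral median VRM at
  a 21-cell window exceeds the background median, and the gap shrinks by a
  101-cell window as windows mix coral and background.

# Raster formats

No GDAL binding is assumed. Single-band rasters (heights, labels, scalars)
read and write ESRI ASCII grids (`.asc`), a plain-text GIS interchange
format that embeds the georeference and nodata sentinel and round-trips
doubles exactly; RGB orthomosaics use TIFF with an ESRI world file
(`.tfw`) and a small JSON sidecar for the nodata sentinel; PNG label masks
are accepted and inherit their georeference from a paired raster. The
package's grid convention is cell-centered: pixel `(row, col)` maps to
world `(x0 + (col - 0.5) cell, y0 - (row - 0.5) cell)`, making
raster-cloud-mesh correspondence unambiguous. Nodata defaults are -9999
for continuous rasters and 255 for labels. Point clouds and meshes use
ASCII PLY with per-vertex `class_id`, scalar and color properties; binary
PLY is not supported.

# Known limitations

* The `full` preset is provided for completeness but is not exercised by
  the CPU-scale test suite; no pretrained weights ship with the package.
* Vertical-ray mesh projection is exact only for height-field meshes.
* Nodata-strict VRM windows shrink the valid area by the window radius;
  large windows on holey DSMs can void substantial area.
* The synthetic generator's colonies are hemispherical with periodic ridge
  texture; real Pocillopora colonies are rougher and more varied, so
  absolute VRM/roughness values in synthetic scenes are indicative only.
* One coordinate frame is assumed throughout; there is no reprojection
  between coordinate reference systems and no multi-tile mosaicking.
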