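---
title: "Methods: multi-output U-Net segmentation and quantification of tangle fluorescence"
author: "tangleseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-output U-Net segmentation and quantification of tangle fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Triple-label immunofluorescence of post-mortem brain tissue from tauopathy
patients (Alzheimer's disease, progressive supranuclear palsy, tangle-only
dementia, frontotemporal dementia) images neurofibrillary tangles (NFTs) in
three colour channels, each channel reporting an antibody against a
different pathological post-translational modification of the tau protein
(or a fibrillar-form dye such as thiazine red). The biological quantity of
interest is the *joint* signal: which parts of a tangle core are positive
in a given combination of channels. With three channels there are four
informative combinations — RG, RB, GB and RGB — and `tangleseg` segments all
four simultaneously and quantifies each as the fraction of image pixels it
covers.

## The network

The segmentation model is a semi-Siamese U-Net: a single convolutional
encoder (contracting path) shared by four parallel decoders (expanding
paths), one per channel combination. Sharing the encoder lets all four
tasks learn one feature representation of the tangle morphology, while the
separate decoders let each combination specialize its upsampling pathway —
the design rationale for preferring it over a single four-channel-output
U-Net.

Concretely, with the default configuration:

* Input: a 3-channel 256 × 256 image with intensities in [0, 1].
* Encoder: 5 levels (the deepest is the bottleneck). Each level applies two
  5 × 5 same-padded stride-1 convolutions with ReLU; between levels a 2 × 2
  max-pool halves the raster, followed by dropout at rate 0.2. The filter
  schedule is 16/32/64/128/256.
* Decoders (× 4): at each level, nearest-neighbour upsampling doubles the
  raster; the decoder concatenates *its own copy* of the same-level encoder
  feature map (skip connection), applies two 5 × 5 convolutions with ReLU,
  then dropout. A final 1 × 1 convolution with sigmoid yields the
  probability map, binarized at a strict `> 0.5`.

The builder is decoder-count-generic: `n_outputs = 1` produces a classical
U-Net with identical hyperparameters, which is the natural single-task
baseline.

Because no deep-learning framework is part of this package's dependency
footprint, the layers (im2col + GEMM convolution, max-pooling with argmax
routing, nearest upsampling) and their reverse-mode gradients are
implemented in RcppArmadillo, with Adam and the training loop in R. The
backward pass is verified against central-difference numerical gradients in
the test suite; this is the strongest available correctness guarantee for a
hand-rolled network.

Numerical choices:

* ReLU gradients use the `> 0` subgradient; max-pool ties route the
  gradient to the first maximum (column-major order).
* Probabilities are clipped to `[1e-7, 1 - 1e-7]` inside the cross-entropy.
* The loss across the four outputs is the unweighted mean of the per-output
  pixel-mean binary cross-entropy; no inter-output weighting is applied
  because none is biologically motivated.
* Dropout is inverted dropout (kept units scaled by `1/(1-rate)`), active
  only during training.

### Initialization

The default initializer is fan-based Glorot uniform
(`limit = sqrt(6/(fan_in + fan_out))`). A fixed-limit uniform(−1, 1) scheme
(`init_scheme = "uniform_pm1"`) is also provided; with 5 × 5 kernels its
variance is far above the Glorot scale and it destabilizes early training,
so it is not the default. Initial weights are materialized once from
`init_seed`, persisted, and reloaded in every cross-validation fold, so all
folds start from bit-identical parameters.

## Training protocol

* Deterministic k-fold cross-validation (default k = 5) under `split_seed`.
  97 items cannot be partitioned into five folds of exactly 19: the
  partition yields validation sizes 19/19/19/20/20, and the 78-train /
  19-validation fold of the original protocol is realized by the
  19-validation folds. A strict partition was chosen over a repeated 80/20
  resample so that every image is validated exactly once.
* Adam with learning rate 5e-4 (beta1 0.9, beta2 0.999, eps 1e-8 — only the
  learning rate is treated as tuned), 50 epochs, mini-batches of 4,
  reshuffled each epoch under `shuffle_seed`.
* Augmentation (training folds only, never validation): each sample yields
  four — the original; a copy rotated by one angle drawn uniformly from
  {90°, 180°, 270°}; an elastic deformation of the original; an elastic
  deformation of the rotated copy. A 78-image fold thus becomes 312
  training images. Augmentation is applied once, offline, so the epoch
  data are fixed.
* Elastic deformation: a per-pixel uniform displacement draw in [−1, 1]²,
  smoothed with a Gaussian of sd `elastic_sigma` (truncated at 4σ,
  edge-replicated borders) and scaled by `elastic_alpha`. Defaults α = 34,
  σ = 4 — the classic values from the elastic-augmentation literature; the
  original study does not state its values, so these are exposed as
  parameters. One field warps the image (bilinear) and all four masks
  (nearest-neighbour, re-binarized), keeping image–mask registration.
  Out-of-border lookups replicate the edge pixel to avoid introducing dark
  borders that would bias mask statistics.
* Right-angle rotations are exact index permutations (no interpolation).

## Evaluation

Four pixel-set metrics per image per output: TP = |GT∩SR|/|GT|,
FP = |SR\GT|/|GT|, Dice = 2|GT∩SR|/(|GT|+|SR|), IoU = |GT∩SR|/|GT∪SR|.
Records are averaged per fold over all validation images and the four
outputs; the summary reports the mean and the sample (n−1) standard
deviation over the fold means. Design choices the original protocol leaves
open, decided here:

* Per-image averaging (not pixel pooling) within a fold — the most common
  reading of averaging "along the four outputs".
* Empty ground truth: TP/FP are undefined (reported `NA`, excluded from
  fold means); Dice/IoU are 1 when both masks are empty, 0 when exactly
  one is. This avoids division-by-zero poisoning of fold averages while
  still penalizing spurious segmentations of empty targets.
* FP can exceed 1 when the spurious area outgrows the target; it is
  reported unclipped.

## Quantification

For each channel combination the segmented pixel count is divided by the
mask's own pixel total (65,536 at the 256 × 256 working resolution) and
reported as a percentage — exactly, so `percent × total / 100` recovers the
integer count. Reports can be computed from model predictions or directly
from ground-truth masks; on generator output the RGB percentage can never
exceed any pairwise percentage because the RGB mask is nested in each.

## The synthetic data generator

The study's clinical images are restricted, so the package ships a
generator that emulates their geometry: `n_cores` isotropic 2-D Gaussian
"tangle cores" (uniform centre; uniform radius, profile σ = radius/2) on a
noisy background, each core present in each channel independently with
probability `channel_presence_probs` and a per-channel peak drawn from
`core_intensity_range`; channels combine by pixelwise maximum, Gaussian
noise is added, and intensities are clipped and quantized to the 8-bit
grid so that the in-memory raster equals its PNG round-trip. Ground truth
for combination C is the set of pixels exceeding `intensity_threshold`
(default 0.5 of dynamic range — a hard stand-in for the experts'
"significant intensity" judgment) in *every* channel of C, inside some
core footprint. This guarantees the nestedness RGB ⊆ RG ∩ RB ∩ GB and makes
the masks exactly recomputable from the stored images.

What the generator does not emulate: confocal point-spread functions,
autofluorescence texture, anisotropic tangle shapes, annotation
disagreement between raters. Passing tests on synthetic data therefore
demonstrate that the pipeline's mechanics are correct, not that the
reported clinical-level accuracy transfers to real acquisitions.

## Scaled-down demonstration conditions

The packaged end-to-end demonstration (and `scripts/acceptance.R`) trains
at reduced scale chosen to exercise every stage on one CPU: 64 × 64
synthetic images, `base_filters = 8`, 30 samples split 24/6 (80/20), 10
epochs, batch 4, Adam 5e-4, no augmentation of the reduced run. The
generator is set to an easy-contrast regime — 5 cores of radius 12–20 px
present in all three channels, peaks 0.9–1.0, noise σ = 0.005, giving
roughly 25% positive pixels per combination — because at desk scale the
learning signal, not the ceiling of the architecture, is what is being
demonstrated: with the generator's sparser default coverage (~2% positive)
the 60 Adam updates of this budget leave the network still in its
all-background phase, whereas the easy-contrast regime is learnable within
it. With every core present in every channel the four decoder targets
nearly coincide; that is acceptable here because this run checks learning
dynamics, while the multi-output mechanics (decoder independence, four
distinct maps) are verified structurally in the unit tests. Full-scale
defaults (256 × 256, 16 base filters, 50 epochs, augmentation on) remain
the package defaults.

## Known limitations

* Training is single-threaded CPU; the default 256 × 256 / 50-epoch
  protocol is hours of compute, not minutes.
* The loss is plain BCE; class-imbalance-aware losses (Dice loss, focal
  loss) are out of scope, matching the original protocol.
* No early stopping or learning-rate schedule; the epoch budget is fixed.
* Physical pixel size varies per acquisition (26.97–134.85 μm fields at
  512 × 512); percentages are therefore relative to image area, not μm².
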