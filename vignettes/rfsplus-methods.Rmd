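---
title: "Region-focused selection ensembles: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-focused selection ensembles: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rfsplus)
```

## The problem

Gliomas are delineated on four co-registered MRI modalities (T1, T1ce, T2,
FLAIR) into three nested evaluation regions: the enhancing tumor (ET), the
tumor core (TC = ET plus necrosis, which closely matches the clinically
contoured gross tumor volume), and the whole tumor (WT = TC plus edema).
Ground truth uses the non-overlapping BraTS codes 0/1/2/4 (background, NCR,
ED, ET). Two practical obstacles dominate transfer to clinical data: MRI
intensities are not standardized across scanners, and no single network
head ("segmentation approach") is best for every region.

Region-focused selection (RFS+) addresses both by brute diversity: train a
grid of U-net candidates crossing *segmentation approaches* — multi-class
(softmax over the four exclusive labels), multi-label (three sigmoid
channels, one per overlapping region), binary (one sigmoid channel for one
region) — with *intensity normalizations* (Z-score; Nyul piecewise-linear
histogram standardization); score every candidate per region on an internal
held-out split; keep the top three for the target region; and combine them
by Dice-weighted probability averaging,

$$p(v) = \sum_{i=1}^{3} w_i\, p_i(v), \qquad
  w_i = \frac{\mathrm{DSC}_i}{\sum_j \mathrm{DSC}_j},$$

thresholded at 0.5. The predecessor (RFS) combines three fixed candidates
by mask union instead; both combiners are implemented.

One genuinely open encoding question is what a "multi-class" head should
predict: the package commits to the four mutually exclusive *labels*
(background, NCR, ED, ET) — the non-overlapping-mask reading — rather
than softmax over the three overlapping regions, which would contradict
exclusivity. Region probabilities for a multi-class candidate are then
derived sums, e.g. $p(\mathrm{TC}) = p(\mathrm{NCR}) + p(\mathrm{ET})$,
which is also how heterogeneous members are put on a common footing
before weighting.

## Candidate networks

All candidates are encoder–decoder U-nets: `depth` blocks of
(conv 3^d → batch norm → ReLU) ×2 followed by 2× max pooling, a bottleneck,
then mirrored 2× transposed-convolution upsampling with skip-connection
concatenation, a 1×1 output convolution and the approach's head. Feature
widths start at `base_channels` and double per level; the canonical 2D
configuration (base 64, depth 4) has widths 64–512 and a 1024-channel
bottleneck. Three input variants exist: 2D (4 channels, one per modality),
2.5D (12 channels: for each modality the slice triplet N−1, N, N+1,
modality-major, with all-black padding at the volume ends), and 3D
(4-channel volumetric patches, brain-centroid-centered, zero-padded).

The implementation is the package's own compact CPU engine
(RcppArmadillo, im2col + GEMM, double precision) with exact analytic
backpropagation — unit tests compare every layer and the whole network
against numerical differentiation. Choices the architecture description
leaves open are fixed as the canonical ones: 3×3(×3) kernels, "same"
zero padding (so the output grid always equals the input grid), 2×
pooling/upsampling, skip fusion by concatenation, He-normal weight
initialization, batch-norm `eps` 1e-5 / momentum 0.1, no dropout.
Training uses Adam (β = 0.9/0.999), the approach-matched loss
(multi-class cross-entropy for softmax; pixel-mean binary cross-entropy
per channel for sigmoid heads, averaged over the three regions in the
multi-label case), probabilities clipped at 1e-7 before logarithms, and
final-epoch weights (no early stopping — the reference recipe specifies
none). Full-scale defaults are 100 epochs / batch 16 / lr 1e-4 for
2D/2.5D and 150 / 4 / 1e-4 for 3D.

## Normalization

*Z-score*: per volume and modality, subtract the mean and divide by the
standard deviation over the brain mask (statistics over the mask, not the
grid — skull-stripped data makes the background an uninformative zero
plateau); background stays 0. Exactly invariant to positive affine
intensity changes.

*Nyul*: per modality, foreground percentiles at ranks
{1, 10, 20, …, 90, 99} are computed on each training volume, affinely
mapped so the outer landmarks hit the standard range (0, 100), and
averaged rank-wise into a standard scale (strictly increasing by a tie
bump of 1e-8·range). Application maps a volume's own landmarks onto the
scale piecewise-linearly, extrapolating with the outer segment slopes
(clipping available via `clip = TRUE`). The ranks and range are the common
configuration of the normalization literature; the source recipe does not
state them, so both are arguments. Landmarks are fitted on the training
split only and the fitted patient ids travel with every trained candidate;
evaluation refuses patients the landmarks saw (leakage guard). An affine
scanner effect is undone exactly at the landmarks, which is the property
the tests assert on phantom pairs.

## Evaluation

Dice, sensitivity and specificity are voxel-count ratios; the both-empty
Dice convention is 1 (a correct "no tumor" call), and empty denominators
yield `NA` rather than 0 or 1. HD95 uses Euclidean distances between voxel
centers scaled by the physical spacing, computed with an exact separable
distance transform. The printed formula for HD95 literally takes a
percentile of the two-element set {max-min, max-min}; the standard reading
— the 95th percentile (linearly interpolated) of *each* directed distance
distribution, combined by the maximum — is implemented as the default,
with the pooled-percentile variant available via `method = "pooled"`.
Distances use all positive voxels, not only boundary voxels.

## Data handling

Patient-level splitting is 70/15/15 (train/validation/internal test) after
a seeded shuffle; the rounding rule (round-half-up on train and
validation, remainder to test) reproduces 70/15/15 at n = 100 and
14/3/3 at n = 20, and refuses cohorts so small a partition would be empty
(n < 6). Candidates are *selected* on the internal test split (the
"unseen 15%"); the validation split is used only for loss monitoring, and
optionally as the weight source (`weight_source = "train"`) since the
training patients themselves are off limits to the leakage guard.
Augmentation (training slices only) applies independent horizontal and
vertical flips at p = 0.5 and rotation uniform in ±15° — the reference
recipe names the three transforms but no rotation range; ±15° is
configurable. Images are interpolated bilinearly, targets by nearest
neighbor, so encodings stay binary/one-hot and region nesting survives;
multi-class pixels rotated in from outside the grid become background.

## The phantom generator

Real BraTS data cannot ship with a package, so every stage is exercised on
synthetic phantoms: an ellipsoidal brain containing nested ellipsoids —
whole tumor (edema shell), tumor core, and a necrotic core whose rim is
the enhancing tumor — guaranteeing ET ⊆ TC ⊆ WT by construction. Per-tissue
modality contrast follows the clinical signature (ET bright on T1ce, tumor
bright on FLAIR; the default table is a package fixture, only the ordering
is normative), modulated by a smooth random quadratic bias field (±10%),
additive Gaussian noise (sd 4 against tissue contrasts of 20–50), and a
per-patient affine scanner effect (gain 0.8–1.25, offset ±10) — the
minimal model of inter-scanner intensity variation. Tumor volume is
4–12% of the brain. Every patient is a deterministic function of
(seed, index).

What the phantoms do *not* emulate: real anatomy and texture, infiltrative
boundaries, partial-volume effects, non-affine scanner differences,
resolution/slice-thickness variation, or registration error. Passing the
phantom study therefore demonstrates that the pipeline's machinery —
encodings, normalization, training, selection, weighting, combination,
metrics — is correct and that the networks can learn, not that clinical
accuracy figures transfer.

## Scaled-down study sizes

The in-package experiment (tests and `scripts/acceptance.R`) runs the full
strategy at desk scale, a deliberate package choice so the study completes
on one CPU: 15 phantoms on a 64×64×24 grid; a 2×2 candidate grid
({multi-label, binary} × {Z-score, Nyul}) of tiny 2D U-nets (base 8,
depth 3); 10 epochs, batch 16, learning rate 3e-3, augmentation off. The
larger learning rate is part of the same scaling: with two orders of
magnitude fewer optimization steps than the full recipe, the tiny task
needs correspondingly larger steps, and 3e-3 converges smoothly here.
Multi-class is exercised structurally in unit tests but kept out of the
tiny grid: separating the rare NCR/ET classes under a plain pixel-mean
cross-entropy needs far more than 10 epochs, mirroring how the
multi-class cells are also the weak rows of the full-scale comparison.
Selection still has the four candidates it needs (minimum three), both
normalizations, and heterogeneous heads to align via region probabilities.

## Known limitations

* The CPU engine is for desk-scale and correctness work, not full-scale
  BraTS training.
* Ensembling operates within one variant's grid (2D *or* 2.5D *or* 3D),
  matching the strategy; cross-variant ensembles are out of scope.
* No DICOM ingestion or RTSTRUCT export; volumes are used in array index
  space (a consistent orientation across modalities is assumed, as holds
  for phantoms and BraTS-style inputs).
* `sensitivity`/`specificity` return `NA` on empty denominators; summaries
  use `na.rm = TRUE`.
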