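---
title: "Monte Carlo dropout segmentation of pericardial fat: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo dropout segmentation of pericardial fat: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pericardial adipose tissue (PAT) — the fat surrounding the heart's surface —
is a candidate cardiovascular risk marker, but measuring it at cohort scale
requires an automated, radiation-free method. `patmc` quantifies PAT as a
single en-bloc 2-D area (cm²) on a four-chamber bSSFP cine CMR frame, taken
at phase 1 of the cardiac cycle (approximately end-diastole), where fat
appears as high signal hugging the epicardial surface of both ventricles.
Bright signal over the liver looks similar but lies below the diaphragm and
must not be included — any automated method has to learn that exclusion, and
any synthetic benchmark has to test it.

Because a fraction of automated segmentations in any large cohort will fail,
the method carries its own quality control: it predicts the Dice score of
each segmentation it produces, without access to ground truth, so poor cases
can be flagged and excluded downstream.

## The model

The segmenter is a multi-residual U-shaped encoder–decoder. Each MultiRes
block chains three 3×3 convolutions (with `W = alpha * U` filters split
roughly 1/6, 1/3, 1/2, `alpha = 1.67`); their concatenated outputs are
batch-normalised and summed with a 1×1 convolutional shortcut. Encoder and
decoder are joined by Res paths: `L` repeated units of a 3×3 convolution
plus 1×1 shortcut with `F` filters, with `L` shrinking for deeper (shorter)
skips. A final 1×1 convolution and sigmoid produce a per-pixel foreground
probability.

The defining modification is a **permanently active spatial dropout layer
(rate r = 0.3) at the end of every MultiRes block**. Dropout is never
switched off — not at inference, not when computing the training loss — so
the network is a stochastic function: every forward pass is a Monte Carlo
(MC) sample from an approximate posterior over segmentations. Batch
normalisation uses running estimates at inference, so dropout is the sole
source of inference-time stochasticity; the variance-shift pathology of
combining batch norm with dropout does not arise precisely because dropout
is never turned off.

From `N` samples (default 15), thresholded at 0.5 into Boolean maps `S_i`,
the package computes:

* **Consensus**: `S(x) = 1` iff `mean_i S_i(x) >= 0.5` — voxelwise majority,
  with `>=` at the boundary so an even split votes foreground.
* **Area with uncertainty**: per-sample foreground area in cm² (pixel count
  × pixel area / 100); reported as mean and sample SD over the N samples.
* **Quality score**: the mean pairwise Dice between samples,
  `d_mc = 2/(N(N-1)) * sum_{i<j} Dice(S_i, S_j)`, linearly corrected to a
  predicted true Dice (`clip(intercept + slope * d_mc, 0, 1)`). The
  correction is fitted by ordinary least squares on held-out validation
  cases — never the test set. Classes: poor (< 0.6), medium (0.6–0.8), good
  (>= 0.8), applied to the corrected value. The alternative statistic, the
  global IoU of all samples (`IoU^G`), is computed for comparison but does
  not drive the classes.

## Training recipe

Binary cross-entropy, Adam (initial LR 0.01, β₁ = 0.9, β₂ = 0.999), batch
size 8, at most 300 epochs. The learning rate is multiplied by 0.3 whenever
10 consecutive epochs pass without a new strict minimum of the monitored
loss; 20 such epochs stop training and restore the best-loss weights. The
monitored loss defaults to the training loss (the recipe names no validation
split for scheduling); `monitor = "validation"` switches to a held-out loss.
Because dropout is always on, the training-mode loss and the inference-mode
model are the same object.

Inputs are resampled to 1.82 × 1.82 mm spacing (bilinear, pixel-centre
convention, edge-clamped), centre cropped/padded to 208 × 208 (zero fill,
extra pixel trailing), and min–max normalised to [0, 1]. Masks travel back
to source geometry by inverting those steps with nearest-neighbour
interpolation. Augmentation applies, jointly and on every draw, the four
transforms of the recipe — rotation up to 25°, isotropic resize up to 20%,
shear up to 20%, per-axis pan up to 25% of the image dimension — sampled
uniformly within symmetric bounds and composed into one affine map about
the image centre (image: bilinear; mask: nearest). On-the-fly sampling
means every epoch sees different warps.

## Implementation notes

No deep-learning framework is involved: the network is a small reverse-mode
tape (R) over Rcpp/Armadillo kernels (im2col + GEMM convolutions, 2×2 max
pooling, 2×2-stride-2 transposed convolutions for learned upsampling, batch
norm). The backward pass is verified against central finite differences in
the test suite (relative error < 1e-4 on sampled parameters). All
randomness — initialisation (He-normal), shuffling, augmentation, dropout —
flows through R's session RNG, so a fixed seed makes training and
segmentation bit-identical on one machine.

Design choices made where the architecture description was open:

* Exact per-level filter counts are configurable; defaults double `U` per
  level with a `2 * max(U)` bottleneck, four encoder levels.
* Dropout is spatial (channel-wise): element-wise dropout after batch norm
  is only weakly stochastic, while channel dropout gives the sample
  diversity the QC statistic needs.
* Upsampling is a learned 2×2 transposed convolution (stride = kernel, so no
  checkerboard overlap).
* The boundary of a mask is its foreground pixels with a 4-neighbour outside
  the foreground (image edge counts as outside); the mean contour distance
  pools both directed boundary-distance sums weighted by boundary size; the
  Hausdorff distance is the max-based symmetric form (no percentile
  variant).
* Dice of two empty masks is defined as 1, one-empty-one-not as 0; the
  probability threshold and the consensus vote both use `>=` at exactly 0.5.

## The phantom generator

Real cohort images cannot ship with a package, so `patmc` ships a seeded
generator of four-chamber-like phantoms on which every stage is trainable
and testable: a dark background; a mid-intensity multi-lobed "heart"
(overlapping ellipses with a thin dark septal line); a bright crescentic fat
band of configurable thickness and angular extent hugging the inferior
epicardial border — the ground-truth target, whose area is exact by
construction; and, with probability 0.7, a bright "liver" ellipse below the
heart that is never part of the truth, testing the sub-diaphragmatic
exclusion rule. A single `difficulty` knob in [0, 1] maps to fat contrast
(0.92 − 0.38 d against a 0.45 heart), Gaussian blur (0.4 + 1.6 d px) and
additive Gaussian noise (0.02 + 0.12 d): difficulty 0 is trivially
segmentable, difficulty 1 has fat barely distinguishable from myocardium.
Noise is Gaussian rather than Rician — adequate at desk scale.

What the phantoms do **not** emulate: anatomical variability of real
four-chamber anatomy, bSSFP banding and flow artefacts, vendor intensity
profiles, cine temporal dynamics, or the fuzzy partial-volume border of real
fat. Passing the package's property tests therefore demonstrates that the
pipeline's machinery — training, MC sampling, consensus, QC calibration —
behaves as designed, not that the shipped defaults reach any particular
accuracy on clinical data, which requires training on real annotated
images.

## Desk-scale study conditions

The end-to-end tests and `scripts/acceptance.R` run the whole pipeline at a
scale chosen for a single CPU: 64 × 64 phantoms at 1.82 mm; reduced network
width `U = (6, 12, 24, 48)`, `F = U`, `L = (4, 3, 2, 1)`, r = 0.3; 200
training phantoms with difficulty in {0, 0.1, 0.2, 0.3}, batch 8, up to 30
epochs; a 50-phantom matched holdout; a 60-phantom calibration set and a
120-phantom test set spanning difficulty {0, 0.25, 0.5, 0.75, 1} at N = 15.
Under these conditions the trained model reaches held-out consensus Dice
around 0.98, the predicted-vs-true Dice correlation is strongly positive,
accuracy degrades monotonically with difficulty, and the gain in consensus
Dice from N = 15 to 30 is smaller than from N = 2 to 5 (the N-sweep reuses
one set of `max(N)` draws per case, subsetting the first N, so the plateau
comparison is not confounded by fresh sampling noise). The N-sweep and
degradation checks use, respectively, the matched holdout and the
mixed-difficulty test set — the distributions on which those questions are
scientifically meaningful.

## Known limitations

* 2-D single-frame only; no short-axis stacks, no volumetric PAT.
* No bias-field correction or multi-vendor intensity harmonisation beyond
  min–max normalisation.
* The DICOM reader handles uncompressed little-endian monochrome files
  only; compressed transfer syntaxes need prior conversion (e.g. to NIfTI).
* Pure-R + BLAS training is desk-scale: full-width 208 × 208 training at
  cohort scale is out of scope.
* The linear QC correction is model- and domain-specific: recalibrate
  whenever the network or the image distribution changes.
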