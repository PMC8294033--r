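# patmc

Automated, quality-controlled quantification of **pericardial adipose tissue
(PAT)** on four-chamber cine cardiovascular magnetic resonance (CMR) frames.

PAT — the fat surrounding the heart — is a candidate cardiovascular risk
marker, but manual contouring does not scale to population cohorts. `patmc`
segments an en-bloc PAT area (cm²) on a single four-chamber bSSFP frame
(phase 1 ≈ end-diastole) with a convolutional network whose defining trait
is a **permanently active dropout layer** (spatial dropout, r = 0.3) at the
end of every multi-residual block. Because dropout never switches off, each
forward pass is a Monte Carlo sample `S_i` of the segmentation, and from
N = 15 samples the package derives:

* the **consensus mask** — voxelwise majority vote,
  `S(x) = 1  iff  (1/N) Σᵢ Sᵢ(x) ≥ 0.5`;
* the **area with uncertainty** — mean ± SD of the per-sample foreground
  areas (pixel count × pixel area, in cm²);
* a **predicted Dice score** — the mean pairwise Dice between samples,
  `d^MC = 2/(N(N−1)) Σ_{i<j} Dice(Sᵢ, Sⱼ)`, passed through a linear
  correction fitted on validation cases, classifying each result as poor
  (< 0.6), medium (0.6–0.8) or good (≥ 0.8) so failures can be flagged
  without ground truth.

The package is self-contained for development and testing: it ships the
network (a tape-based autograd over Rcpp/Armadillo kernels — no external
deep-learning framework), the training recipe (binary cross-entropy, Adam,
LR × 0.3 after 10 stagnant epochs, early stop after 20, best-weights
restore), on-the-fly affine augmentation, the four agreement metrics (Dice,
IoU, mean contour distance, Hausdorff, in mm), Bland–Altman and Pearson
harnesses, and a **seeded phantom generator** producing four-chamber-like
images with exact ground truth, a liver-like bright distractor that must
not be segmented, and a difficulty knob for QC experiments.

## Worked example

Desk-scale end to end (64 × 64 phantoms, reduced width; ~6 min to train on
one CPU):

```r
library(patmc)

pcfg <- phantom_config(image_shape = c(64, 64))
ncfg <- network_config(base_filters_U = c(6, 12, 24, 48),
                       respath_filters_F = c(6, 12, 24, 48),
                       respath_length_L = c(4, 3, 2, 1))

train_ds <- generate_dataset(pcfg, 200, c(0, 0.1, 0.2, 0.3), seed = 101)
set.seed(7)
fit <- train(build_network(ncfg), train_ds,
             training_config(max_epochs = 30, rng_seed = 11),
             acfg = augmentation_config())

# QC calibration on a held-out validation spectrum (never the test set)
val <- generate_dataset(pcfg, 60, c(0, 0.25, 0.5, 0.75, 1), seed = 303)
cal <- cmd_calibrate(fit$model, val, n_mc = 15, seed = 13)
cal
#> <qc_calibration> predicted_dice = -0.4053 + 1.4179 * d_mc  (n = 60, r = 0.966)

# Segment unseen images of graded difficulty
test <- generate_dataset(pcfg, 4, c(0, 0.4, 0.7, 1), seed = 505)
cmd_segment(test, fit$model, cal, n_mc = 15, seed = 99)
#>           source_id area_mean_cm2 area_sd_cm2  d_mc  iou_g predicted_dice quality flagged
#> 1 phantom-563118340          5.06      0.0389 0.997 0.9610          1.000    good   FALSE
#> 2 phantom-429070139          4.29      0.4124 0.930 0.5769          0.913    good   FALSE
#> 3  phantom-88983836          2.36      0.7893 0.686 0.0833          0.568    poor    TRUE
#> 4 phantom-748101808          1.08      0.6521 0.406 0.0069          0.170    poor    TRUE
```

Read the rows top to bottom as difficulty rises: the easy case recovers its
true area (5.07 cm²) with a tight MC spread and predicted Dice 1.0; as fat
contrast falls the samples disagree (`d_mc` drops, area SD grows) and the
QC flags the failing segmentations — exactly the behaviour the predicted
Dice exists to provide. On a mixed-difficulty test set the predicted and
true Dice correlate strongly (Pearson r ≈ 0.95–0.99 at this scale).

Held-out accuracy of the same model, and the agreement/plotting harnesses:

```r
evaluate_epoch(fit$model, generate_dataset(pcfg, 50, c(0, 0.1, 0.2, 0.3), seed = 202))
#> [1] 0.9831431

sweep_n_samples(fit$model, hold_ds, c(2, 5, 15, 30), seed = 19)   # N plateau
ba <- bland_altman(report$area_mean_cm2, test$true_area_cm2)      # agreement
autoplot(ba); autoplot(cal); autoplot(fit)
```

A thin shell dispatcher wraps the same functions
(`inst/cli/patmc.R phantom|train|calibrate|segment|evaluate|sweep-n|sweep-dropout`).

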