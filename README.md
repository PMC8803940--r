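# brainseg

Whole-brain segmentation of T1-weighted MR volumes assigns every voxel to an
anatomical region (cortical parcels, subcortical nuclei, ventricles, white
matter).  Head motion during acquisition leaves ghosting and ringing
artifacts in the image, and different segmentation methods lose consistency
at different rates as image quality degrades.  `brainseg` is an R package
for studying exactly that: it implements a two-stage convolutional
segmentation pipeline, a synthetic head-motion study generator, and a
reliability-evaluation framework that compares segmentation methods across
graded image-quality tiers with nonparametric statistics.

It is written for methods researchers in neuroimaging who want a fully
self-contained, CPU-sized, reproducible testbed: every component — including
the 3D convolution engine the networks run on — is in the package, and every
experiment is driven by a single run seed.

## What is inside

**The segmentation pipeline.**  An input volume is conformed (cubic-spline
resampling to 1 mm isotropic, centered crop/pad to a fixed grid, N(0,1)
intensity normalization over the whole array).  Stage 1 downsamples the
volume by 0.5 and regresses the tight brain bounding box
`(i0, j0, k0, d_i, d_j, d_k)` with a 16-convolution network (Swish
activations, L1L2 penalties, stride-2 reductions, no pooling; Adam with the
schedule `lr0 * r^(epoch/s)`, `r = 0.92`, `s = 10`); only the predicted
center is kept, and a fixed 152 x 152 x 184 box (15.2 cm lateral and
inferior-superior, 18.4 cm anterior-posterior at 1 mm) is placed around it.
Stage 2 tiles the cropped block with 27 overlapping subvolumes (half-shape
windows at quarter-shape steps), scores each with a U-Net-style
encoder-decoder (conv + batch-norm only, skip connection, Swish), merges
overlapping scores by coverage-weighted averaging, takes the voxelwise
argmax, and pads the result back to the full extent with the Unknown label.
Training optimizes the sum of focal loss (alpha = 4, gamma = 2) and
generalized Dice loss with RMSprop.

**The synthetic study.**  Labeled ellipsoidal head phantoms (scalp, four
cortical quadrant parcels, white matter, ventricles, four deep-gray nuclei,
T1-like tissue contrasts plus Gaussian noise) stand in for non-public motion
data.  Motion artifacts are simulated in k-space: contiguous blocks of
phase-encode lines are re-acquired under random rigid poses (translations as
exact phase ramps, rotations by resampling), emulating 5-nod and 10-nod
acquisition conditions; a monotone severity score grades each record into
quality tiers HM1 (good) / HM2 (medium) / HM3 (bad).

**The evaluation framework.**  Per-region Dice, Jaccard, Hausdorff distance
(boundary voxels, mm) and relative volumetric difference `|Vg - Vp|/Vg`;
head-motion pairing (motion-free HM1 record as reference vs every motion
record) and test-retest pairing (all within-subject pairs, earlier record as
ground truth); region averages per (subject, method, macro-region, pairing
type); two-sided Wilcoxon signed-rank or Mann-Whitney U comparisons with
Benjamini-Hochberg correction per metric at alpha = 0.05.  The framework is
method-agnostic and consumes NIfTI masks from any tool.

## A worked example

The end-to-end demonstration trains both networks on desk-scale phantoms
(64^3 grid, 40 x 40 x 48 crop box, same 27-subvolume structure as full
scale), simulates a head-motion study for 8 subjects, segments every record
with the trained pipeline and with a nearest-tissue-mean baseline, and runs
the head-motion reliability evaluation:

```r
library(brainseg)
res <- run_demo("demo_out", seed = 1)
aggregate(dsc ~ pairing_type + method, data = res$summary, FUN = mean)
```

```
  pairing_type       method       dsc
1      HM1-HM1          cnn 0.8097390
2      HM1-HM2          cnn 0.7380108
3      HM1-HM3          cnn 0.6254621
4      HM1-HM1 nearest_mean 0.7002160
5      HM1-HM2 nearest_mean 0.6105791
6      HM1-HM3 nearest_mean 0.4954737
```

Reading the table: each row is the mean Dice similarity coefficient between
the mask of a subject's motion-free reference record and the mask of a
motion record of the given quality tier, averaged over regions, subjects and
macro-regions.  Consistency decreases monotonically as artifact severity
grows (HM1-HM1 >= HM1-HM2 >= HM1-HM3) for both methods, and the trained
pipeline is more consistent than the intensity-only baseline at every tier —
the qualitative pattern such reliability studies are designed to expose.
`res$stats` holds the per-metric Wilcoxon/Mann-Whitney comparisons with
BH-adjusted p-values, and `demo_out/` the tidy CSV tables
(`region_metrics.csv`, `summary.csv`, `stats.csv`) plus the resolved run
configuration.

A command-line front end wrapping the same functions ships in
`inst/cli/brainseg` (subcommands `simulate`, `train-crop`, `train-seg`,
`predict`, `evaluate`, `compare`, `demo`).

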