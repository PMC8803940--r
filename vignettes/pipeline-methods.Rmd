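---
title: "Two-stage whole-brain segmentation and its reliability evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage whole-brain segmentation and its reliability evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(brainseg)
```

## The problem

Whole-brain segmentation assigns every voxel of a T1-weighted MR volume to an
anatomical region (cortical parcels, subcortical nuclei, ventricles, white
matter).  Head motion during acquisition corrupts the k-space data and
produces ghosting and ringing artifacts that degrade segmentation quality,
and different segmentation methods degrade at different rates.  `brainseg`
implements, in one package:

1. a **two-stage convolutional segmentation pipeline** — a localization
   network that places a fixed-size bounding box around the brain, and an
   encoder–decoder network that segments overlapping subvolumes of the
   cropped block whose merged predictions are padded back to the full field
   of view with the Unknown label;
2. a **synthetic study generator** — labeled head phantoms plus a segmented
   k-space rigid-motion simulator that produces graded image-quality tiers
   (HM1/HM2/HM3) and repeated sessions; and
3. a **reliability-evaluation framework** — per-region similarity metrics
   (Dice, Jaccard, Hausdorff distance, relative volumetric difference),
   head-motion and test–retest pairing designs, averaging within
   subject/method/macro-region/pairing cells, and nonparametric method
   comparison (Wilcoxon signed-rank / Mann–Whitney U) with
   Benjamini–Hochberg correction per metric.

The evaluation framework is method-agnostic: it consumes NIfTI masks from
any segmentation tool, so external pipelines can be compared by pointing a
roster at their outputs.  Masks are assumed co-registered; the package
checks geometric consistency but does not register.

## The pipeline

### Conforming preprocessing

Inputs of any voxel size are resampled to 1 mm isotropic with separable
natural cubic-spline interpolation, center-cropped/zero-padded to a fixed
grid (256³ at full scale), and intensity-normalized to zero mean and unit
variance over the whole array, background included.  Conforming is
idempotent, so already-conformed volumes pass through unchanged.

### Stage 1: bounding-box localization

The conformed volume is downsampled by a factor 0.5 (cubic spline, shared
origin, so a downsampled coordinate `x` maps to `x / 0.5` at full
resolution) and fed to a regression network that predicts the 6-vector
`(i0, j0, k0, di, dj, dk)` of the tight box around all non-Unknown voxels
of the training mask.  The architecture is 16 convolutional layers
(3³ kernels, SAME padding, Swish activations `x·sigmoid(x)`, L1L2 weight
penalties of 0.01 each, all spatial reduction by stride-2 convolutions —
no pooling), two hidden dense layers, and a linear 6-unit output.
Training minimizes the mean squared error with Adam under the exponential
schedule `lr0 · r^(epoch/s)` with defaults `lr0 = 10e-4` (taken literally
as printed, i.e. 1e-3; the alternative reading 1e-4 is one config field
away), `r = 0.92`, `s = 10`, mini-batches of 8 and early stopping with
patience 20.

Only the predicted box **center** is used downstream: a fixed-size box of
152 × 152 × 184 voxels (15.2 cm lateral and inferior–superior, 18.4 cm
anterior–posterior at 1 mm; the anterior–posterior direction is always the
third array axis in the package's canonical `RSA` orientation) is placed
around it, shifted — never shrunk — to lie inside the volume, so the
cropped block shape is constant regardless of the input.

### Stage 2: overlapping-subvolume segmentation

The cropped block is tiled by subvolumes of half its shape sampled at
quarter-shape steps: per axis the starts are `0, step, 2·step, …` with the
last start forced to `extent − sub_shape`, giving 3 starts per axis and
27 overlapping subvolumes at the default geometry.  Each subvolume is
scored by an encoder–decoder network in the U-Net family: two
convolutional blocks at full resolution, a stride-2 convolutional
downsampling stage, a bottleneck block, nearest-neighbour upsampling with
a convolutional block, a concatenating skip connection from the encoder, a
decoder block, and a linear 1³ output convolution; every convolution is
followed by batch normalization and Swish, and there are no pooling
layers.  Per-voxel scores of the 27 subvolumes are merged by summing into
a full-extent accumulator and dividing by the per-voxel coverage count
(1–8 subvolumes depending on position); the voxelwise argmax (ties broken
deterministically to the lowest class index) yields the cropped mask,
which is embedded into the full extent with the Unknown label outside the
box.

Training iterates over the grid subvolumes of the cropped pairs with
RMSprop, mini-batches of 2 subvolumes, and early stopping with patience
25.  As online augmentation each pair is, with probability 0.3, rotated
identically by per-axis angles drawn from [−1, 1]° about the volume center
displaced by integer offsets from [−2, 2] voxels (trilinear for
intensities, nearest-neighbour for labels; all three axes are rotated,
with independently sampled angles).

### The objective

The loss is the weighted sum (1:1 by default; both weights configurable)
of

* **focal loss**, `mean(−α (1−p_t)^γ log p_t)` with `α = 4`, `γ = 2`,
  which down-weights voxels that are already classified confidently and
  concentrates the gradient on hard and rare classes; and
* **generalized Dice loss**,
  `1 − 2 Σ_l w_l Σ_v p_lv y_lv / Σ_l w_l Σ_v (p_lv + y_lv)` with
  inverse-square-count weights `w_l = 1/(n_l + ε)²`, which balances
  classes of very different volumetric size.

One numerical choice deserves emphasis.  A class absent from a subvolume's
truth (`n_l = 0`) would receive weight `1/ε²`, about twelve orders of
magnitude above any present class; the loss gradient is then almost
entirely about suppressing rare labels wherever they are absent, and in
pilot runs no small structure was ever predicted.  The package therefore
caps absent-class weights at the largest present-class weight — the
standard stabilization used by public generalized-Dice implementations.
Present-class weights follow the formula unchanged.

With `α = 1, γ = 0` the focal term reduces exactly to mean cross-entropy;
the composite loss is zero precisely for the one-hot truth (up to the ε
terms).  Both facts are enforced by tests, and the full backward pass of
both networks is verified against central finite differences.

## The synthetic study

### What the phantom emulates

A phantom is a labeled ellipsoidal head: a scalp shell (Unknown label,
nonzero intensity — so the localization task is nontrivial), a cortical
ribbon split into four quadrant parcels, a white-matter core, paired
ventricles, and four ellipsoidal subcortical nuclei on a ring inside the
white matter.  Tissue mean intensities (arbitrary T1-like units: CSF 30,
scalp 45, cortical parcels 55–79, deep-gray nuclei 78–105, white matter
125) approximate the relative T1 contrast ordering CSF ≪ cortical gray <
deep gray < white matter, with additive Gaussian noise (default sd 4, a
comfortable but not trivial contrast-to-noise ratio).  Anatomy is jittered
per subject (center, overall scale, nucleus angles); like real subcortical
anatomy, the nucleus arrangement itself is stereotyped across subjects —
real nuclei do not permute their positions, and a convolutional network
legitimately uses that regularity.

The phantom deliberately does **not** model MR physics: no sequence
simulation, no bias field, no partial-volume mixtures, no coil or
parallel-imaging model, and its geometry is far simpler than a real brain
(convex shells instead of folded cortex).  Passing tests on phantoms
therefore demonstrate that the pipeline's mechanics — geometry, losses,
optimization, merging, padding, evaluation — work end-to-end and that the
networks can learn tissue contrast and stereotyped spatial layout; they do
not certify segmentation accuracy on real MR images.

### Desk-scale geometry

All experiments in the tests run at a desk scale chosen once: 64³ phantoms
with a 40 × 40 × 48 crop box (the full-scale box scaled by ¼ and rounded
to multiples of 4 so the subvolume grid tiles evenly), subvolumes
20 × 20 × 24, steps 10 × 10 × 12, and the same 27-subvolume structure as
the full geometry.  One deliberate deviation from strict ¼ scaling: the
nuclei are about 8 voxels across (≈ 400 voxels) rather than the ≈ 5 voxels
strict scaling would give.  At 5 voxels a structure is at the resolution
limit of any voxelwise method, which tests the grid size rather than the
pipeline; at full scale a thalamus spans ~15 voxels, and the desk nuclei
are sized to remain comparably resolvable.  Training sizes used by the
test suite and demo (20 training phantoms for the recovery runs, 8 for
the demo; 8 epochs with 12 randomly sampled subvolumes per volume per
epoch; RMSprop learning rate 3e-3 from pilot convergence runs) are the
package's defaults for this scale.  The 256³ / 152 × 152 × 184 geometry
remains the documented default for real data.

### Motion simulation and quality tiers

An MPRAGE-like acquisition fills k-space line by line along one
phase-encode axis (anterior–posterior here).  A "nod" between segments
leaves a contiguous block of lines acquired in a displaced pose.  The
simulator partitions about `corrupted_fraction` of the phase-encode lines
into `n_nods` contiguous blocks; per block a rigid pose is drawn
(translations enter exactly as linear phase ramps, rotations by
image-domain resampling before the transform), the corresponding k-space
lines are replaced, and the magnitude of the inverse transform is
returned.  This produces the characteristic ghosting/ringing of
interrupted acquisitions while conserving image energy to within 1%
(phase-only corruption), and never touches the ground-truth mask.

Severity is summarized as
`corrupted_fraction · (max_translation_mm + (50π/180) · max_rotation_deg)`
— rotations converted to an equivalent edge displacement at a 50 mm head
radius — and graded into tiers by two thresholds (0.5 and 2.0, calibrated
once against the generator's two motion conditions; ties grade to the
better tier).  The study generator gives every subject a motion-free CONV
record and two motion records: a 5-nod condition (fraction 0.25,
1.2 mm / 1.2° peaks) and a 10-nod condition (fraction 0.5, 2.5 mm / 2.5°),
each scaled by a per-record factor drawn from [0.5, 1.5].  The 5-nod
condition straddles the first threshold (so a realistic minority of its
records still grade HM1) and the 10-nod condition concentrates in HM3,
mirroring the qualitative tier mix of radiologist-rated motion studies.
The paper-scale magnitudes per nod are not published; these are free
parameters of the generator, chosen once.

### Seeding

One run seed deterministically derives the seed of every stochastic
component (`derive_seed(seed, key, ...)`): phantom anatomy, noise draws,
motion block placement and poses, network initialization, shuffling,
augmentation, subvolume subsampling.  Two runs with the same seed produce
identical tables; repeated sessions of one subject share the anatomy seed
and differ only in the noise seed.

## Evaluation and statistics

Per region (never the Unknown label), both masks are binarized and four
metrics computed: Dice `2|A∩B|/(|A|+|B|)`, Jaccard `|A∩B|/|A∪B|`
(`iou = dsc/(2−dsc)` identically), the symmetric Hausdorff distance
between boundary voxels in mm (boundary = inside voxel with a 6-neighbour
outside; a 95th-percentile variant is available but non-default), and the
relative volumetric difference `|V_g − V_p|/V_g` with the reference as
ground truth.  Undefined values — Hausdorff with an empty region, VD with
an empty reference — are flagged `NA` and excluded from averages with
explicit exclusion counts, never silently dropped, since silent dropping
would bias summaries invisibly.

The head-motion design uses each subject's motion-free record (if graded
HM1) as the reference and pairs it with every motion record
(`HM1-HM1`, `HM1-HM2`, `HM1-HM3` pairing types); subjects without an HM1
reference are excluded with a logged reason.  The test–retest design pairs
every two records of a subject, the earlier acting as ground truth.
Metrics are averaged across regions within (subject, method, macro-region,
pairing type) cells; two methods are compared per metric, macro-region and
pairing type with a two-sided Wilcoxon signed-rank test when both cover
identical subject sets, and a two-sided Mann–Whitney U test otherwise
(the designs naturally produce unequal pair counts when one method fails
on some records).  All-zero paired differences are degenerate and flagged
instead of tested.  Raw p-values are Benjamini–Hochberg-adjusted within
each metric's family, with significance at adjusted p < 0.05.

## Label schemes

The default segmentation target has 50 entries in total: Unknown (id 0),
34 cortical parcels merged across hemispheres, 11 subcortical/cerebellar
structures, and 4 further classes including a single merged ventricle
label — a Desikan–Killiany-style target with hemisphere-merged labels.
Whether such a 50-region count includes the background label is a
convention; this package counts Unknown among the 50.  Schemes are plain
text (`id name macro_region`; FreeSurfer-LUT column order accepted) and
fully user-replaceable, and `merge_labels()` applies arbitrary merge maps
with strict checking (every present label mapped, every target in the
scheme).

## Design choices where the design was open

* **Merge normalization**: "adding and normalizing" overlapping scores is
  implemented as coverage-count averaging of raw scores before the argmax.
  Softmax renormalization yields the same argmax wherever coverage is
  uniform; averaging also keeps the merged scores on the scale of a single
  subvolume's scores.
* **Tie-breaking**: argmax ties go to the lowest class index,
  deterministically.
* **Border handling**: a fixed box that would protrude is shifted inside
  the volume, not truncated, preserving the constant input shape the
  segmentation network requires.
* **Downsampled regression frame**: the 6-vector is predicted in the
  downsampled frame and rescaled by `1/0.5` before the fixed box is
  placed; targets are in raw voxel units (no [0, 1] normalization).
* **Upsampling**: nearest-neighbour ×2 followed by a convolution (the
  common transposed-convolution alternative adds parameters without
  benefit at these widths).
* **Batch-norm**: statistics are computed per input block during training
  (running moments, momentum 0.1, used at inference); with mini-batches of
  2 subvolumes this is close to instance normalization, standard in
  volumetric segmentation.
* **Exact layer widths**: the published structural constraints (16 conv +
  2 hidden dense for the localization net; encoder–decoder with skip
  connections, conv + batch-norm only, for the segmenter) are enforced
  structurally, while channel counts and stride placement are configurable
  defaults (doubling widths, four stride-2 reductions).
* **Hemispheric merge maps and scheme content** are configuration, not
  code.

## Known limitations

* The CPU engine is built for desk-scale experiments; full-scale (256³)
  training is supported in form but would be impractically slow on one
  core — the full geometry is intended for inference-style use and for
  geometric checks.
* The phantom's simplicity means cortical-boundary accuracy claims cannot
  be transferred to real data.
* Rigid registration is out of scope; inputs to the evaluation must be
  co-registered already (consistency is checked, not corrected).
* The radiologist quality rating behind real HM tiers is replaced by a
  deterministic severity score; the mapping is monotone but not a model of
  human rating.
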