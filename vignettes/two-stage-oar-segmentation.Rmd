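---
title: "Two-stage organ-at-risk auto-segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage organ-at-risk auto-segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Radiotherapy planning for pediatric craniospinal irradiation requires
contours for many organs at risk (OARs) — from paired lenses of a few
voxels to lungs of tens of thousands — on whole-body CT. Training one
multi-class network on full-resolution whole-body scans is dominated by
class imbalance and memory; `csiseg` instead splits the task in two stages,
both cheap enough to train and run on a CPU:

1. **Localization.** Digitally reconstructed radiographs (DRRs) are
   synthesized by clipping the CT to a tissue-specific contrast window and
   summing along an axis. A 2D single-box detector finds the organ on a
   pair of orthogonal DRRs, and the two boxes are fused into a 3D region of
   interest (ROI): lateral extent from the coronal view, anterior-posterior
   and superior-inferior extent from the sagittal view.
2. **Segmentation.** A small organ-specific U-Net segments the organ inside
   a normalized, padded crop of the CT around the ROI (a "mini-CT"),
   slice by slice in the axial plane. Predictions are thresholded at 0.5,
   reduced to their largest 26-connected component, and pasted back into
   the whole-body frame.

Body structures (lungs, esophagus, spinal canal target, vertebral bodies,
kidneys, brain, brainstem) are detected coronal-first: the sagittal DRR is
then restricted to the lateral extent of the coronal detection so that
irrelevant anatomy does not contaminate the projection. Small head
structures (eyes, lenses, optic nerves, chiasm, cochleae) use a different
route: the head region is delimited by the inferior border of the
brainstem, bone-window sagittal DRRs are built separately for the left and
right half of the head (split at the body-mask lateral centroid column),
and the axial DRR is summed over the detected superior-inferior extent.
Head reference boxes are doubled in height and width, because at these
sizes the box would otherwise carry almost no context.

## Shared preprocessing

All volumes pass through the same preprocessing regardless of the model
that consumes them: voxels outside the body are forced to −1000 HU; the
patient is centered on a fixed axial canvas (512 × 256 pixels, lateral ×
anterior-posterior, at full scale); overlapping labels are made mutually
exclusive by cropping each smaller structure out of the larger one it
overlaps (lens out of eye, spinal canal out of vertebral column, brainstem
and the optic apparatus out of brain); heterogeneous test data are
resampled with nearest-neighbor interpolation, for the image as well as
the masks, so that masks stay strictly binary. Clinical body contours are
not available to the package, so the body mask is derived: voxels above
−300 HU, largest 26-connected component, axial-slice hole filling (the
threshold is a configuration key).

Arrays are kept in a single canonical axis order `(z, y, x)` — superior to
inferior, anterior to posterior, patient-left to right — and any on-disk
NIfTI orientation is converted exactly once at load time. Coordinates in
boxes and ROIs are half-open, 0-based pixel intervals; detector-native
encodings (normalized center/size) are converted at the contract boundary.

## Contrast windows and DRR normalization

Three scalar windows are used: lung [−1500, 0] HU, soft tissue [0, 50] HU,
bone [250, 3000] HU, plus a composite window that stacks the three as
image channels. After summation each DRR is min–max normalized to 0–255
per image; a fixed global scale was rejected because projection sums grow
with body thickness, which varies several-fold across a pediatric cohort.
An all-constant projection (e.g. an empty crop) maps to an all-zero image
so that degenerate inputs remain representable. Rounding is half-to-even,
which keeps DRRs bit-stable across platforms. Per-organ window defaults:
lung window for the lungs, bone for the vertebral column, spinal canal and
all head structures, composite elsewhere; all overridable.

## Detectors

The localization design is deliberately detector-agnostic: any model that
returns one box with a confidence (or a "not found" signal) through
`predict_box()` satisfies the contract, and a ground-truth-backed
`oracle_detector()` is provided to exercise the geometry independently of
learning. The built-in reference detector is a small convolutional box
regressor written directly in R (BLAS-backed conv/pool/dense layers):
the DRR is resized to 64 × 64, two coordinate channels are appended (a
regression head needs an explicit notion of position), three conv/pool
stages feed a dense head that outputs a normalized center/size box and a
presence logit. Training uses Adam on a mean-squared coordinate loss plus
a presence term, with joint translation augmentation of the image and its
box target — with a dozen training images per organ and plane, translation
augmentation is what makes the regressor generalize rather than memorize.
Defaults follow the protocol of batch size 32 with up to 600 epochs; the
phantom studies use 150 epochs at batch size 6, which is where the
held-out box error stops improving on this data. A detector below the 0.5
presence confidence reports "not found", which is recorded per organ and
patient rather than raised as an error.

Axial context margins are added to the fused ROI on each side in y and x:
+20 pixels for the lungs, +15 for the spinal canal target, vertebral
bodies, kidneys and esophagus, +10 for brain and brainstem, none for head
structures (their boxes are already doubled). The superior-inferior extent
is taken from the sagittal box as-is: the margins are read as an
axial-plane operation, and growing z as well would mostly import unrelated
anatomy into the crop. ROIs exceeding the per-organ maximum crop size are
shrunk symmetrically about their center; the maxima default to the
per-organ maxima observed on the training cohort plus margins (a
configuration override exists, since a site with an external size table
would use that instead).

## Mini-CT normalization

Body organs clip HU to a per-organ range computed by the percentile rule:
the lower bound is the smaller of the 10th percentile inside the reference
mask and the 10th percentile in a 2 mm rim around it (morphological
dilation minus the mask, with the rim radius converted to voxels per axis
by rounding up); the upper bound is the larger of the two 90th
percentiles. At inference no reference mask exists, so the per-case ranges
from the training cohort are frozen into one organ-level range as the
median of the lows and the median of the highs. Head structures use a
fixed 0–250 HU window. Values are mapped linearly to [0, 1] *before*
zero-padding to the organ's uniform crop size, so the pad value 0
coincides with the clip minimum and the network sees a constant
background. A degenerate constant range is widened by ±1 HU.

## Segmentation models and training

Three variants share one encoder–decoder backbone with skip connections,
trained on axial slices: a basic U-Net (single-channel slices), an
attention U-Net that gates each skip connection with an additive attention
block before concatenation, and a 2.5D variant — the same 2D network fed a
3-channel sandwich of the superior neighbor, target, and inferior neighbor
slice, predicting the mask of the middle slice only; at the volume ends
the missing neighbor is edge-replicated. The exact reference architecture
is not public, so depth and width are configuration; the defaults (two
pooling levels, base width 8; width 16 for the tiny head crops) are the
smallest networks that saturate held-out accuracy on the phantom tasks.
No deep-learning framework is available to R in this environment, so the
layers (3×3/1×1 convolution, 2×2 max pooling, nearest-neighbor
upsampling, the attention gate, dense heads) are implemented directly as
BLAS matrix products with hand-derived backward passes, verified against
central finite differences in the test suite.

Training minimizes soft-Dice plus binary cross-entropy with Adam
(learning rate 1e-3) — the loss and optimizer are package choices, stated
in `train_config()`. Augmentation follows the protocol of ±15° in-plane
rotation and ±15% isotropic scaling applied with 50% probability, jointly
to image and mask (bilinear vs. nearest resampling). Outputs pass through
a sigmoid; voxels strictly above 0.5 are foreground; the largest
26-connected component is kept, with equal-size ties broken toward the
component containing the lexicographically smallest `(z, y, x)` voxel.
Every stochastic step (initialization, shuffling, augmentation) draws from
a seeded stream, making the full simulate → preprocess → localize → train
→ infer → evaluate chain bit-for-bit reproducible on CPU.

## Evaluation and statistics

Segmentation accuracy is the 3D Dice similarity coefficient with a
smoothing term, `(2|A∩B| + ε) / (|A| + |B| + ε)` with ε = 1e-7, which
keeps the metric defined (and equal to 1) when both masks are empty.
The statistical suite over DSC tables mirrors standard practice for model
comparison studies:

* **Between models:** a Kruskal–Wallis H test per organ, Holm–Bonferroni
  adjusted across organs at α = 0.05; organs surviving adjustment get
  Dunn's pairwise post-hoc z tests on the joint ranks (with tie
  correction), reported unadjusted within the organ's family by default
  (a configuration switch enables within-family adjustment). Adjusted
  p-values are clipped to 1.
* **Trend with age:** the original Mann–Kendall test on the DSC sequence
  sorted by age, per model and organ, with Benjamini–Hochberg FDR across
  the batch (the FDR procedure is a package choice; τ is reported as
  `S / (n(n−1)/2)`, matching concordant-minus-discordant pair counting).
* **Follow-up group splits:** two-sided Mann–Whitney U between patients
  younger than 10 years and 10 or older (age exactly 10 goes to the older
  group, following the interval convention), unadjusted; and
  validation-versus-test cohort comparisons per model and organ with FDR
  control. Exact U distributions are used for small samples, the
  tie-corrected normal approximation otherwise.

## The synthetic phantom cohort

Everything above is trainable and testable without patient data because
the package ships a whole-body phantom generator with exact ground-truth
masks. A phantom is a soft-tissue body (≈30 HU) in −1000 HU air: lungs at
−800 HU; an air tube (−900 HU, a trachea analog) directly anterior to a
soft-tissue esophagus tube; a +700 HU vertebral column with an embedded
≈20 HU spinal-canal analog; kidneys at 35 HU wrapped in a −100 HU fat rim
whose thickness grows with age (mirroring the age-dependence of perirenal
fat); and a head with a bone skull shell, brain, brainstem, orbital fat
(−80 HU) cradling 20 HU eyes with 60 HU lenses, optic-nerve tubes meeting
at a chiasm, and +500 HU cochlear bone points. HU means sit in standard
tissue ranges chosen so the three contrast windows separate the intended
structures; all are configuration. Organ sizes scale linearly in the cube
root of target volume with a synthetic age covariate (so volumes scale
roughly linearly with age), ages are drawn uniformly per cohort, and
additive Gaussian noise of 8 HU emulates CT noise. All draws come from
per-phantom seeds derived from the cohort seed.

The phantom emulates contrast relationships and gross topology, not
anatomy: there is no scanner physics, no metal artifact, no pathology, no
inter-patient shape variation beyond global scale, and intensity
boundaries are crisper than real tissue interfaces. Passing the phantom
studies therefore demonstrates that the machinery is correct and that the
two-stage design can recover organs that are identifiable from intensity
and context; it does not certify clinical accuracy on patient CT.

## Problem sizes and numerical choices

The packaged validation study uses a 16-phantom cohort (12 training, 4
held out — matching the scale of a small external test set) on a
160 × 96 × 96 voxel grid at 2 mm isotropic spacing, ages 3–18 years; one
body organ (left kidney) and one head organ (left eye) are trained end to
end, plus all three variants on the kidney crops. Detector training runs
150 epochs at batch size 6 (the small batches add the gradient noise
that helps a dozen-image training set generalize); segmenters run 10
epochs at batch 12 (body) and 40 epochs at batch 8 (head — the head
crops are an order of magnitude smaller, so the longer schedule is
nearly free). The localization containment property is
checked with ground-truth-backed detectors on a separate 20-phantom
cohort at 120 × 72 × 72. These sizes are the package's validation
conditions; all are arguments to `run_phantom_study()`.

Other numerical conventions: percentiles use the standard linear
interpolation definition; centering uses the body-mask centroid rounded
toward negative infinity; nearest-neighbor index maps use the half-pixel
convention `src = floor((i + 0.5) · n_in / n_out)` (so integer upsampling
duplicates slices exactly); DRR rounding is half-to-even; the Mann–Kendall
z statistic carries the ±1 continuity correction.

## Known limitations

* The built-in detector regresses a single box; multi-instance detection
  and rotated boxes are out of scope, and any stronger published detector
  can be substituted through the contract.
* The segmentation stage is 2D/2.5D; a 3D variant is deliberately not
  provided.
* The percentile clip rule is frozen per organ from training cases; a
  cohort whose HU distribution drifts from training (different kVp,
  contrast agent) would need the configuration override.
* Whether the head-structure sagittal boxes should also restrict the
  axial DRR anterior-posteriorly is ambiguous; only the z restriction is
  applied.
* DICOM and RT-Struct handling, dosimetric evaluation, and surface
  distance metrics are not implemented.

## A worked example

```{r example}
library(csiseg)

# a small self-contained study: simulate, train, evaluate
study <- run_phantom_study(n = 8, n_test = 2, seed = 7,
                           organs = "kidney_l", det_epochs = 120)
summarize_dsc(study$records)

# and the statistics layer over any DSC table
trend_with_age(study$records)
```
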