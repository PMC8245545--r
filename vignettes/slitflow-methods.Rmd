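---
title: "Classifying red blood cells at a microfluidic slit barrier: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying red blood cells at a microfluidic slit barrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

The spleen removes aged and defective red blood cells (RBCs) by forcing them
through micron-scale inter-endothelial slits. Cells from patients with rare
hereditary hemolytic anemias (RHHA) — sickle cell disease (SCD), thalassemia
(THAL), hereditary spherocytosis (HS) — lose membrane deformability: after
squeezing through a slit they fail to recover a circular projection, while
healthy cells recover almost immediately. A microfluidic chip with a row of
funnel-shaped micro-constrictions reproduces this filtering geometry under a
brightfield microscope, and label-free time-lapse videos of cells crossing
the slit barrier carry enough shape information to classify a *video* (one
donor's recording) as healthy or diseased, and among disease subtypes.

`slitflow` implements the complete analysis: cell localisation by circular
Hough transform, extraction of fixed-size regions of interest (ROIs) around
each cell on the downstream side of the barrier, coding of every ROI into a
numeric descriptor vector, unsupervised low-variance feature elimination,
linear one-vs-all SVM scoring under leave-one-experiment-out (LOEO)
cross-validation, and cooperative aggregation of per-ROI decisions into one
video-level diagnosis. Because the patient recordings are not publicly
deposited, the package ships a synthetic video generator with per-cell
ground truth; every stage is tested against it.

## The synthetic video generator

`generate_video()` renders grayscale frames (bright background, gray level
0.85) containing a dark vertical band of micro-constrictions and
quasi-circular cells advected left to right. Defaults mirror the recording
conditions the pipeline targets: ~1000 frames per video at 85 frames/s,
cells of projected radius 8 ± 0.8 px, per-cell velocity 2 ± 0.4 px/frame,
additive Gaussian noise (sd 0.02 gray levels) and occasional mild defocus
(probability 0.02 per frame). Test runs and the bundled analysis scripts
pass smaller `n_frames` (40–120) explicitly; that choice only shortens the
recording, it does not alter per-frame statistics.

Shape dynamics follow the deformability contrast the chip is built to
expose. Every cell is rendered as an area-preserving ellipse whose
eccentricity depends on its position: inside the band all cells elongate to
eccentricity 0.85 (everything deforms in a slit); past the band the
eccentricity relaxes exponentially toward a target with a class-specific
relaxation length. Normal cells relax to 0.15 within ~4 px (about half a
cell diameter — prompt recovery); abnormal cells keep their projection
(relaxation length effectively infinite) with class-specific targets:

| class | abnormal projection |
|---|---|
| healthy "old" cell | moderately elongated (eccentricity 0.45) |
| SCD | strongly elongated (0.80), slightly larger |
| THAL | irregular boundary (±5% radius wobble), internal dark inclusion, eccentricity 0.50 |
| HS | small (0.65× radius), round (0.10), higher contrast |

Each video draws its cells' abnormal flags from a per-video
`abnormal_fraction`: 0.05 for controls (old cells exist in every donor) and
0.8 for patients (transfusion therapy and disease heterogeneity mean not
every cell is abnormal). These mixtures are the *realistic* regime; a
*strongly separated* cohort (fractions 0 and 1) is available through
`generate_cohort(..., abnormal_fraction = c(healthy = 0, SCD = 1, ...))`
and is what the end-to-end property checks use, since they assert
near-perfect video-level behaviour rather than the paper-scale error rates.

No quantitative per-class morphology statistics exist for the real
recordings, so the class margins above are free design parameters chosen
once: large enough that the four models are geometrically distinct, small
enough that per-ROI classification stays imperfect (shape recovery is
gradual, mixtures are impure and noise is present) — which is precisely the
regime the cooperative video-level rules are designed for. What a passing
test shows, therefore, is that the *pipeline* recovers class structure that
the generator put in; it says nothing about the discriminability of real
patient cells.

The ground truth records every cell's per-frame centre, projected
eccentricity, in-frame flag and an overlap mark (centres closer than the
sum of radii), plus per-cell morphology parameters. Frames are quantised to
8-bit levels at generation time so TIFF/PNG writers round-trip them
bit-exactly; the whole video is a deterministic function of its seed, and
cohorts derive per-video seeds from a single cohort seed.

Aspects of real recordings the generator does not emulate: flow-rate
fluctuations and cell stalling in the slits, out-of-plane rotation and
focus drift, illumination gradients, debris, and cell–cell hydrodynamic
interactions. Overlaps occur (and are truth-marked) but collisions do not
alter trajectories.

## Coordinates and cropping

All coordinates are 1-based `(row, col)` matrix indices, the natural R
convention. `crop_to_barrier_region()` keeps the inclusive column window
`[barrier_x - half_width, barrier_x + half_width]` (so a half-width of 100
yields 201 columns and the barrier lands on column `half_width + 1`); the
applied offset is retained so ground truth can be shifted alongside. The
default half-width of 72 px spans many relaxation lengths downstream, so
transitional (still-relaxing) appearances of healthy cells are a small
minority of post-barrier ROIs. `estimate_barrier_x()` locates the barrier
automatically as the minimiser of the column-smoothed temporal-mean
intensity profile — the constriction row is the darkest persistent vertical
structure — and declares an estimation error on flat profiles.

## Cell localisation

`detect_cells()` is a classical circular Hough transform with
gradient-direction voting. Sobel edge pixels above
`max(quantile(|∇I|, 0.9), 0.2)` vote at every integer radius in the search
range along the *negative* gradient direction (cells are dark on a bright
background, so centres lie against the gradient). The accumulator is
smoothed with a 3×3 box, normalised by the circle circumference 2πr, and
local maxima above `sensitivity = 0.3` survive. Non-maximum suppression is
radius-aware: a kept detection suppresses weaker peaks within its own
radius, and a candidate whose circle reaches a kept centre (a "ghost ring")
is dropped; the floor is `r_min`. The radius range defaults to the
configured mean cell radius ±50%, reflecting the tight physiological size
distribution of RBCs. Detections are ordered by descending score with ties
broken by (row, col).

`detect_video()` first subtracts the per-pixel temporal median (up to 50
sampled frames) so static structures — above all the barrier band itself —
contribute no votes; this is standard fixed-stage time-lapse practice, not
a special case in the detector.

There is deliberately no tracking and no cross-frame deduplication: a cell
is sampled once per frame it is visible, so slow or stalled cells
contribute more ROIs, exactly as in the real acquisition. Strongly
elongated in-slit cells are weak circular-Hough responders and receive no
special handling; the analysis consumes post-barrier ROIs where cells are
compact again. Detection quality is therefore scored (recall ≥ 0.95,
centre error ≤ 2 px against generator truth) over compact appearances:
fully in-frame, not overlap-marked, true eccentricity ≤ 0.6.

`extract_rois()` crops a fixed 32 px square around each detection
(zero-padded at frame edges), tags it `after` iff its centre column exceeds
`barrier_x`, and `filter_rois()` keeps the post-barrier side; the pipeline
additionally applies a detection-score floor of 0.5, which removes the
spurious low-score responses a permissive accumulator threshold lets
through.

## Feature coding

Two interchangeable backends produce the per-ROI descriptor row; downstream
stages are backend-agnostic.

The **handcrafted backend** (offline default) thresholds the crop with
Otsu's method — accepting the split only when foreground/background means
differ by ≥ 0.1 gray levels, so blank crops yield a defined all-zero shape
block — selects the largest dark connected component (exact-zero edge
padding excluded, centrality as tie-break), and computes 23 descriptors:
area, perimeter, circularity 4πA/P², moment eccentricity, solidity against
the convex hull, the seven Hu moment invariants, foreground intensity
mean/sd/skewness, and an 8-bin radial intensity profile. Hu moments are
rotation-invariant by construction (tested exactly under 90° rotations).

The **CNN backend** implements transfer-learning coding: the grayscale crop
is bilinearly resized to 224 px, replicated to three channels, and pushed
through an AlexNet-geometry convolutional stack (five convolutions, three
max-poolings, im2col convolution) up to the third max-pooling layer; the
flattened activations — 256 × 6 × 6 = 9216 values, a dimensionality the
package derives from the layer arithmetic rather than hard-coding — are the
feature vector. Weights are only ever read from a local RDS file; nothing
is downloaded and the network is never fine-tuned. Since pretrained
ImageNet weights cannot be shipped, `synthetic_cnn_weights()` writes random
Gaussian weights in the same format so the code path is exercisable
offline; features from synthetic weights are deterministic but carry no
pretrained semantics, which is why the shipped analyses default to the
handcrafted backend. The input preprocessing (resize method, channel
replication, no intensity renormalisation) is a frozen configuration
choice.

## Feature selection

`fit_low_variance_mask()` removes features with small variation over the
dataset — unsupervised, on raw (unstandardised) column variances with
denominator n−1. `threshold` mode keeps columns with variance above a
limit; `target_factor` mode places the threshold at the variance quantile
retaining ⌈n/value⌉ columns (ties keep the lower column index), so the
factor-50 default reduces a 9216-column pool5 coding to 185 columns. Inside
LOEO the mask is fitted per fold on training rows only (leakage-safe); with
the 23-column handcrafted coding the pipeline instead uses a near-zero
threshold that only discards degenerate columns, since a factor-50 cut of
23 columns would be meaningless. Whether the original analysis fitted its
filter globally or per fold is unstated; per-fold is the safe default and a
global fit is a one-liner on the full table.

## Classification and cross-validation

`train_classifier()` standardises features (centre/scale from training
rows — linear SVMs on raw activations are scale-sensitive) and fits linear
SVMs (C = 1 by default, unweighted hinge loss; inverse-frequency weighting
is available). The four-class problem trains one one-vs-all separator per
class; the two-class problem trains a single margin and mirrors it, so a
point on the boundary scores exactly (0.5, 0.5). Decision values map to
normalised scores by a softmax at temperature 1 — monotone in the decision
values and requiring no extra fit inside each fold (a Platt-style
calibration would need one) — and the label is the argmax with ties to the
lower class index. Class labels follow the published coding: healthy 0,
SCD 1, THAL 2, HS 3.

`run_loeo()` holds out all ROIs of one video per fold, exhaustively over
videos. Selection mask, standardisation and SVM are fitted on training rows
only; a fold whose training partition collapses to one class is skipped
with a warning and recorded. The fold manifest retains training-row counts,
whose mean at the published cohort size (79 videos, 3442 post-barrier ROIs)
reproduces the published 3398 training samples. Cross-validation is per
*video*, not per subject: two videos of one donor can appear on opposite
sides of a fold, a leakage the original design accepts and which is noted,
not corrected (the synthetic cohort has one video per "donor", so it is
moot there).

## Cooperative video-level decisions

Three rules aggregate a video's scored ROIs:

* **Majority voting** — the modal per-ROI label; ties break by the larger
  per-class score total, then the lower class index.
* **Unhealthy-percentage limit** (two-class) — unhealthy iff the fraction
  of unhealthy-labelled ROIs *strictly* exceeds the limit (0.30 and 0.40
  are the reference operating points; "exceeds" is read as a strict
  inequality and the boundary case is pinned by a test). The 30% limit is
  the high-sensitivity screening configuration: on separable cohorts it
  produces no false-negative disease videos.
* **Maximum trustiness** — the class with the largest sum of per-ROI
  normalised scores; because each ROI's scores sum to one, the per-class
  sums total the ROI count, and the winning sum divided by the ROI count is
  the video's normalised score (the bar height in a score-profile sketch,
  exported by `score_profile()`).

`build_confusion()` tabulates truth × decided over videos and
`efficiency()` reports the trace over the total — "efficiency" is defined
as video-level overall accuracy, the only reading consistent with the
published matrices (72/79 → 91%, 65/79 → 82%); full precision is kept
internally and `format_efficiency()` rounds for display. Videos with no
post-barrier ROI are undecidable: flagged, excluded from matrices, counted
in the report.

## Numerical and degenerate-input conventions

* All randomness flows from explicit integer seeds; cohort seeds derive
  per-video seeds deterministically.
* Every tie-break is frozen and tested: detection ordering (score, then
  row, col), selection ties (lower column index), score argmax (lower
  class), majority ties (score total, then lower class), trustiness ties
  (lower class).
* Degenerate inputs raise typed conditions (`slitflow_config_error`,
  `slitflow_format_error`, `slitflow_estimation_error`,
  `slitflow_capability_error`, `slitflow_selection_error`,
  `slitflow_training_error`, `slitflow_shape_error`,
  `slitflow_usage_error`, `slitflow_decision_error`,
  `slitflow_consistency_error`) rather than generic failures.
* Constant feature columns get unit scale during standardisation; an
  all-constant matrix is a selection error; a class absent from training
  receives an effectively -Inf bias so its softmax score vanishes.

## Problem sizes in the shipped runs

The bundled analysis scripts simulate a 24-video cohort (9 control / 3 SCD
/ 3 THAL / 9 HS, the published proportions at one-third scale) of 120
frames each under the realistic mixtures; the end-to-end property checks
and the acceptance script use a 12-video strongly separated cohort (6/2/2/2)
of 120 frames, and a sparser wide-field cohort for the per-ROI accuracy
bound. These sizes are the package's own choice of a desk-scale experiment;
statistics per frame and per cell match the generator defaults throughout.

## Known limitations

* The generator's class margins are design parameters, not calibrated to
  patient data; absolute error rates on synthetic cohorts are not
  predictions of clinical performance.
* Under permuted labels, grouped LOEO with bag-level class imbalance sits
  *at or below* chance (the held-out video's label is the training
  minority), so the permutation null is asserted one-sided.
* The CNN backend reproduces the coding architecture but cannot reproduce
  pretrained features offline; the handcrafted backend is the tested
  default.
* AVI input is not supported (no lossless R reader is available); convert
  recordings to multi-page TIFF or PNG frames.
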