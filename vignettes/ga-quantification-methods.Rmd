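---
title: "Rule-based geographic atrophy quantification on SD-OCT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based geographic atrophy quantification on SD-OCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaquant)
```

## The problem

Geographic atrophy (GA), the late lesion of dry age-related macular
degeneration, is defined on OCT by the joint loss of the photoreceptor
ellipsoid zone (EZ) and the retinal pigment epithelium (RPE). When a
multi-layer segmentation places the EZ, RPE and Bruch's membrane (BM)
boundary lines on a B-scan, atrophy shows up as a simple geometric
signature: the three lines coincide, because the EZ-RPE and RPE-BM
thicknesses are zero. `gaquant` turns that signature into a complete
quantification pipeline:

1. **Confluence detection** (`detect_confluence()`): a column is GA
   when both inter-line thicknesses are at or below a tolerance.
2. **Mask dilation** (`build_bscan_mask()`): flagged columns become a
   10-pixel band centred on the BM line, the ground-truth format used to
   train segmentation networks.
3. **En face compilation** (`compile_enface()`): per-B-scan masks are
   reduced by a depth-wise maximum and stacked, one row per B-scan, into
   a top-down GA map.
4. **Lesion morphometry** (`measure_lesions()`): connected components,
   greatest linear dimension (GLD) in micrometres, cRORA/iRORA grading
   at the 250-µm CAM threshold, and GA area as a percentage of scan
   area.
5. **Evaluation** (`pixel_confusion()`, `icc_agreement()`,
   `roc_curve()`, ...): the detection-level, pixel-level and agreement
   statistics used to judge automated GA segmentation.
6. **A desk-scale learner** (`build_model()`, `fit_unet()`,
   `mine_hard_examples()`): an encoder-decoder that learns the same rule
   from image intensity, demonstrating the full train/retrain loop.

Everything is exercised on a synthetic phantom generator
(`simulate_phantom()`), so the whole pipeline is testable without
clinical data.

## Coordinate and geometry conventions

An `oct_geometry` fixes the cube grid. Two presets mirror the common
protocols: `"spectralis"` (97 B-scans × 512 A-scans) and `"cirrus"`
(128 × 512), both over a 6 mm × 6 mm macular field. The Spectralis
field of view is assumed equal to the Cirrus 6 × 6 mm field; both field
dimensions are plain arguments, so other protocols are one call away.
Axial depths default to 496 px (Spectralis) and 1024 px (Cirrus).

All public indices are 0-based; row 0 is the vitreous side of a B-scan;
boundary rows are sub-pixel reals; pixel membership uses half-open
intervals and pixel centers. En face pixel spacing is strongly
anisotropic — about 11.7 µm along a B-scan versus 46.9-61.9 µm across
B-scans — which drives two design choices below.

## The phantom generator

`simulate_phantom()` emulates exactly the features the pipeline
consumes, and nothing more:

* **Lesions** are ellipses in physical en face coordinates; the full
  major axis is drawn uniformly (default 100-600 µm, spanning the CAM
  threshold), aspect ratio 0.4-1, orientation uniform. Centers are
  rejection-sampled so lesions remain disjoint components.
* **Layer boundaries** ride a smooth low-frequency undulation (a seeded
  sum of three separable sinusoids, default peak 6 px) with fixed
  healthy separations (EZ-RPE 8 px, RPE-BM 5 px). At any column whose
  en face pixel center lies inside a lesion, all three boundaries
  collapse onto the BM row — zero thickness by construction.
* **Intensity B-scans** are banded reflectivity images; below BM, the
  choroid in atrophic columns is `hyper_gain` (default 2) times
  brighter, emulating hypertransmission, before additive Gaussian noise
  (default sd 0.05). The mean-over-depth projection
  (`enface_intensity()`) therefore shows bright lesions on a darker
  background, the contrast an en face model learns from.
* **Truth** is the analytic footprint (`analytic_enface()`): a pixel is
  positive iff its center lies inside a lesion ellipse. Membership at
  pixel centers (rather than any-overlap) keeps rasterization
  unambiguous and makes the truth map exactly recoverable: the set of
  confluent columns equals the analytic footprint by construction, a
  property the test suite asserts exactly.

The generator does **not** model speckle statistics, drusen, vessel
shadows, motion artifacts or registration error. Consequently, passing
tests show that the pipeline's geometry, bookkeeping and learning loop
are correct — not that the learned model would transfer to clinical
scans, where boundary segmentations carry their own errors.

## Numerical choices

* **Confluence tolerance** `tol_px = 0.5`: boundaries are sub-pixel
  reals, so "zero thickness" is read as below half a pixel. The flagged
  set grows monotonically in the tolerance (tested); integer-valued
  pipelines can set `tol_px = 0` for exact equality.
* **Band convention**: an even dilation thickness cannot be centred
  symmetrically on a row; thickness 10 covers 5 px above the rounded BM
  row and 4 below plus the row itself. Rounding is half-up
  (`floor(r + 0.5)`), not banker's rounding, for platform-stable masks.
* **Horizontal resizing is block maximum**, never interpolation: masks
  are binary and a single-column lesion must survive a 1024-to-512
  resize. Source column `j` belongs to target `floor(j * target / W)`;
  the inverse nearest-source expansion makes
  `compile(project(M)) == M` exact at matched widths (property-tested).
* **Greatest linear dimension**: pixel coordinates are scaled to
  micrometres per axis *before* computing second central moments;
  measuring on raw indices would conflate the ~12 µm fast-axis spacing
  with the ~47-62 µm slow-axis spacing. The GLD is the image-moments
  major axis, `4 * sqrt` of the largest covariance eigenvalue with the
  population denominator — the convention of standard region-properties
  tools. A single-pixel lesion reports `max(um_per_px_x, um_per_px_y)`.
  A maximum-Feret-diameter option is provided for sensitivity analysis;
  on convex blob-like lesions the two differ by a few percent.
  Quantization on the coarse slow axis limits attainable accuracy: on a
  97-row grid a 400-µm disc measures within about half a slow-axis
  pixel (±31 µm) of truth, with a small upward bias on near-circular
  lesions because the maximal eigenvalue of a noisy covariance is
  selected. The package therefore never asserts GLD accuracy tighter
  than the grid's quantization scale, and the cRORA classification test
  excludes a one-coarse-pixel band around the 250-µm threshold.
* **cRORA comparator**: lesions that meet the threshold exactly are
  cRORA (`>=`); a strict comparator is available
  (`classify_cam(strict = TRUE)`).
* **ICC variant**: two-way, absolute-agreement, single measures
  (McGraw-Wong A,1) — the standard for method-versus-truth agreement,
  where a systematic offset should count against the method. The
  consistency variant (C,1) is a switch. Confidence intervals use the
  F-distribution method with Satterthwaite degrees of freedom.
* **ROC pooling** is pixel-pooled across scans, weighting every pixel
  equally; per-scan averaging would up-weight small scans. The curve is
  anchored at (0,0) and (1,1) and integrated by trapezoid.
* **Undefined metrics** (zero denominators) are reported as `NA` with a
  note, never silently dropped; the F-score is 0 when positives exist
  but none are found, and 1 for a perfect empty prediction (used in
  per-item hard-example scoring, where empty-lesion items are possible).

## The learning demonstrator

Two model flavors share one architecture: the **B-scan flavor** pairs
intensity B-scans with the dilated BM-band masks, and the **en face
flavor** pairs mean-projection en face images with the en face GA map.
The network is a symmetric encoder-decoder with skip connections:
`conv_per_block` 5×5 convolutions + ReLU per level, 2×2 max pooling,
nearest-neighbour upsampling, a final 1×1 convolution and sigmoid.
Optimization follows the reference recipe: binary cross-entropy,
RMSProp (decay 0.9, epsilon 1e-8) at learning rate 1e-4, batch size 40,
200 samples per epoch drawn with replacement, early stopping after 7
epochs without validation improvement, best-validation weights
restored.

Hard-example retraining scores a seeded sample of 100 items by pixel
F-score, takes the 30th percentile (linear interpolation — the R
default quantile definition) as a threshold, duplicates every training
item strictly below it (originals retained, order stable), and runs a
second training round continuing from the round-one weights. Because
epoch sampling is uniform with replacement, a duplicated item is seen
twice as often in expectation. "Items" here are whole resized training
images; patch cropping is not modelled.

Two scales are built in. `train_config("paper_scale")` reproduces the
full-size setting — 256-px inputs, depth 4, 32 base filters, classic
double-convolution blocks, about 2.2e7 parameters (asserted only to
the order of magnitude). The default `"desk"` scale — 64-px inputs,
depth 3, 6 base filters, one convolution per block (~9.5e4 parameters),
at most 40 epochs per round — exists so the complete
train/retrain/evaluate cycle runs in CPU-minutes; among desk-size
variants of the architecture this one showed the best
validation-loss-per-epoch behaviour, consistent with the RMSProp
update equalizing per-parameter step sizes so that total movement in
function space scales with the parameter count. Inputs of any
resolution are resized (bilinear) on entry, standardized per image,
and confidence maps are resized back (bilinear) on exit before
thresholding. Upsampling the *confidence*
rather than the binarized mask matters: it interpolates the decision
boundary to sub-model-grid precision and measurably improves pixel
overlap at native resolution. The learned-rule-recovery experiment in
the test suite (60 training / 10 validation / 20 held-out phantoms on a
128×128×128 grid, hypertransmission gain 2, noise 0.05) is this
package's analogue of parameter recovery on simulated data: the truth
maps are generated by the confluence rule, so a sufficiently trained
model must approach that rule's output. All training is exactly
reproducible given the config seed (deterministic convolution kernels,
seeded sampling and initialization).

Because the learning rate is small, the sigmoid outputs stay
under-saturated long after the network separates lesion from
background; the default 0.5 binarization can then sit off the best
operating point. `tune_threshold()` implements the usual remedy: a
threshold sweep maximizing pooled pixel F on the *validation* items
only, never the held-out set. The paper-style fixed 0.5 cut remains
the default everywhere.

`patient_split()` enforces the clinical-data hygiene rule the training
protocol requires — every timepoint of a patient lands in exactly one
of train/validation/test (default 80/10/10, largest-remainder
allocation, realized counts within one patient of target).

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on phantoms:
50 Spectralis phantoms for footprint recovery, 500 single-ellipse
phantoms per device grid for cRORA grading, 100 random instances per
statistical oracle, 1000 random split designs, and one desk-scale
train/retrain cycle (90 phantoms). These sizes were chosen as the
smallest that exercise every code path with stable statistics while
keeping a full run in CPU-minutes.

## Known limitations

* The phantom's layer geometry is smooth and its noise Gaussian; real
  segmentations fail in structured ways (vessel shadows, drusenoid
  elevation) that the rule inherits as errors.
* The en face GA map has B-scan-pitch resolution vertically; very small
  lesions between B-scans are invisible by construction, on real
  devices as here.
* GLD on the coarse slow axis is quantization-limited (see above); near
  the 250-µm threshold, grading from a 47-62 µm grid is intrinsically
  uncertain within about one pixel of the threshold.
* The desk-scale learner shows rule recovery, not clinical performance;
  its accuracy ceiling is set by the 64-px working grid.
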