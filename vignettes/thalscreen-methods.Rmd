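---
title: "Screening for beta-thalassaemia trait from electrophoresis strip images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for beta-thalassaemia trait from electrophoresis strip images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

Haemoglobin electrophoresis separates the haemoglobin variants of a lysed
blood sample along a stained cellulose acetate strip. Each patient's sample
runs in one vertical lane; a scanner-format strip holds up to eight lanes
side by side. Within a lane, the adult variant HbA migrates fastest and
forms the band farthest from the application point, HbA2 migrates slowest
and forms the band nearest to it, and fetal HbF (when present) sits between
them. In a healthy adult HbA2 is under 3.5% of total haemoglobin;
beta-thalassaemia trait — the heterozygous carrier state whose detection
drives population screening — shows a compensatory rise of HbA2, up to
about 7%, sometimes with residual HbF. On a Ponceau-stained strip this
reads as a visibly darker slow band.

`thalscreen` automates the two stages of reading such a strip:

1. **lane extraction** — segmenting the scanned multi-patient strip into
   per-patient lane images by classical image processing, and
2. **classification** — labelling each lane normal or thalassaemia with a
   convolutional network, evaluated under a stratified five-fold
   cross-validation protocol with standard classifier metrics, binomial
   confidence half-widths, ROC analysis and Score-CAM saliency maps.

No patient images ship with the package. Every stage is instead exercised
against a seeded synthetic strip simulator with exact per-lane ground
truth, described last.

## Lane extraction

The segmentation pipeline is deliberately classical, each step with a
small, fixed parameter set:

1. **Grayscale** conversion with BT.601 luma weights (0.299, 0.587,
   0.114) — the de-facto standard; the choice only rotates the threshold.
2. **Complement** (`255 - v`), turning dark bands on the light background
   into bright foreground.
3. **Gaussian blur**, 5×5 kernel. The kernel size is part of the
   protocol; the standard deviation is not stated anywhere, so we use
   `sigma = 1.0`, the conventional choice for which ±2σ spans a 5-pixel
   kernel. Borders are reflected so that the frame of the image does not
   darken and spawn spurious components. The threshold is computed on the
   *blurred* complement: the denoising filter is described as applied to
   the complemented image, so thresholding logically consumes its output.
4. **Otsu's threshold**: the histogram threshold maximizing between-class
   variance, scanned exhaustively over all 256 candidates; ties break
   toward the smallest threshold so the result is deterministic.
   Foreground is `pixel > t`. A constant image has no two classes to
   separate and raises an explicit degenerate-histogram error rather than
   returning an arbitrary value.
5. **Two-scale erosion + compensating dilation**
   (`separate_objects()`): erosion with a 3×3 square, erosion with a 5×5
   square, dilation with the same 5×5 square. Adjacent lanes
   occasionally touch where sample material smears between application
   points; the resulting thin neck joins two lane blobs into one
   connected component, and the two successive erosions cut any neck up
   to ~10 px across while the dilation restores most of the band
   extent. The 5×5 element is protocol; the second scale is not stated,
   and 3×3 is the smallest standard element bracketing it from below.
   Note the composite is *not* idempotent (the uncompensated 3×3 erosion
   shrinks the mask slightly on every pass); it is anti-extensive and
   monotone, which is what the pipeline relies on, and both properties
   are tested.
6. **8-connected component labelling** (union-find, labels in raster
   order of first pixel), followed by an area filter at 0.05% of the
   image — stain specks are orders of magnitude smaller than any band.
7. **Lane boxes**: the bands of one patient stack vertically and share a
   column interval, so surviving components are grouped when their
   column intervals overlap (or come within 2 px, an anti-fragmentation
   tolerance); each group becomes a box spanning the full strip height
   and the group's column extent padded by 2 px. Boxes are 0-based,
   half-open, ordered left to right. If the caller states an expected
   lane count (8 for the standard format) and the detection disagrees, a
   structured warning is attached and raised — never a silent repair.
   An optional equal-width fallback split was considered and rejected:
   guessing silently is worse than reporting.
8. **Crop and resample** each box from the *original RGB strip* to the
   fixed 30×150 RGB classifier input with bilinear interpolation
   (half-pixel-centre convention, so a native-size crop passes through
   pixel-identically). The interpolation method is unstated in the
   protocol; bilinear is the standard default for modest rescaling.

## Augmentation

Training images (and only training images — augmentation happens strictly
after the fold split) are expanded 15-fold: the original plus 14 variants.
Each variant applies exactly one of three geometric strategies, cycled in
the order rotation → scale → translation, with the parameter drawn
uniformly from its range: clockwise rotation of 3–5°, centre-anchored
magnification of 2.5–10% (implicitly centre-cropped back to 30×150), or
horizontal-and-vertical translation by 5–10% of each dimension. The
protocol does not say how the 14 variants are apportioned among
strategies, so the fixed cycle reproduces the stated count without
inventing composite transforms; rotation is taken literally as
clockwise-only, while translation direction (unstated) is drawn at
random. All transforms resample bilinearly with border replication, so
output size and the 0–255 range never change, and the drawn parameters
are recorded on each variant for audit. With 189 training images per
class per fold this yields the protocol's 2835.

## Classifier and cross-validation

The shipped classifier, `tinycnn`, is a compact network trained from
scratch: two 3×3 convolution blocks (8 and 16 channels, ReLU, 2×2 max
pooling) and a linear softmax head over the two classes — about 35k
parameters. Convolution and pooling forward/backward passes are compiled
(Rcpp); the optimizer is Adam at learning rate 0.001, batch size 16, at
most 15 epochs. After each epoch the validation loss drives the schedule:
no improvement for 4 consecutive epochs multiplies the learning rate by
0.1 (the reduction factor is unstated in the protocol; 0.1 is the
standard step), and no improvement for 5 consecutive epochs stops
training. The best-validation-loss weights are kept. Inputs are scaled to
[0, 1]; the decision rule is the softmax argmax.

Larger pretrained backbones are registry-pluggable
(`register_model()`): the package validates their names but ships no
weights, and the entire test surface runs on `tinycnn`.

Folds are stratified per class: a seeded shuffle, then each fold takes a
contiguous rotation of `floor(n/k)` ids as its test set (so test sets are
disjoint and a remainder of `n mod k` ids per class is never tested),
then a fixed number of validation ids from the remaining pool, the rest
training. With 262 images per class, five folds and 21 validation images
this gives the protocol's 52/21/189 per class per fold. The 21-image
validation set (≈10% of the 210 non-test images) follows the tabulated
protocol rather than the alternative reading of "20% of the training
data"; the table is the operative specification. Pooling the per-fold
test predictions tests every retained lane exactly once.

## Evaluation

With thalassaemia as the positive class, TP/TN/FP/FN feed the five
standard metrics (accuracy, recall, specificity, precision, F1), reported
per class and macro-averaged (unweighted mean over the two classes);
accuracy is computed once on pooled counts and does not depend on the
positive designation. Macro averaging is the only averaging rule
consistent with the published precision value, and is documented as such.
Zero denominators yield `NA` markers, never a crash.

Each metric `m` (in percent) carries a binomial normal-approximation
half-width of `z * sqrt(m * (100 - m) / N)` percentage points, `z = 1.96`
for 95%. The operative `N` is the total evaluated count (524) for
accuracy and the per-class count (262) for the class metrics — the unique
assignment that reproduces the published ±1.72 versus ±2.43/±2.42
half-widths, reverse-engineered and labelled as such.

ROC curves sweep all score thresholds; tied scores receive half credit,
making the trapezoidal AUC equal to the Mann–Whitney concordance
probability (verified against an all-pairs oracle and against `pROC`).
Per-fold curves are vertically averaged on a fixed 101-point
false-positive-rate grid. Timing is `delta_te = (t2 - t1) / n_images`
seconds; it is reported only and never asserted against published
hardware-dependent numbers.

## Score-CAM

Saliency uses Score-CAM, which needs no gradients: each channel of a
chosen convolutional activation (default: the last convolutional layer,
standard CAM practice) is min-max normalized, bilinearly upsampled to the
input size, and used to mask the input against a zero baseline; the
masked input's softmax score for the target class is that channel's
weight. The map is the rectified weighted sum of the normalized upsampled
channels, min-max normalized. Degenerate cases are pinned down: constant
channels are skipped, and all-zero activations give an all-zero map. The
implementation is tested to 1e-6 against an independent step-by-step
re-execution of the recipe on a toy two-channel network, and the overlay
renders the conventional blue (low contribution) to red (high
contribution) blend. On trained models, mean saliency inside the band
rows exceeds the outside — the decisions track the bands — asserted on
synthetic data only.

## The synthetic strip simulator

The simulator emulates what the pipeline must cope with, not what a
scanner produces:

- **Geometry.** Default canvas 320×1280 px, eight lanes along the
  columns, migration down the rows from the application point at row 0.
  Each lane's band window occupies 60% of its slot, with ±3 px lateral
  jitter. Strip pixel dimensions are artifact choices — no scanner
  resolution is part of the protocol.
- **Bands.** Each band is a 1-D Gaussian ridge along the rows (sigma a
  fraction of lane length: 0.025 for HbA, 0.020 HbF, 0.018 HbA2) at fixed
  migration positions (fractions 0.78 / 0.55 / 0.30 of lane length for
  HbA / HbF / HbA2, respecting the migration order). Band darkness is
  `255 * min(1, 2.5 * stain)`, so integrated darkness is proportional to
  the variant's stain fraction until the dominant HbA band saturates —
  dark-red bands on a Ponceau-pink background (bands subtract more from
  the green/blue channels than red). Stain fades toward the lane edges
  under a cosine taper (8 px), giving the rounded blob outlines real
  stained bands have.
- **Classes.** Stain fractions sum to 1 per lane. Normal lanes draw HbA2
  from 1.5–3.4% (below the 3.5% carrier cutoff) and carry no HbF;
  thalassaemia lanes draw HbA2 from 4–7% (the carrier range) and carry an
  HbF band of 3–12% with probability 0.5. HbA takes the remainder. These
  defaults are the study conditions; the well-separated configuration
  used by the end-to-end accuracy property narrows them to 0.5–1.5%
  versus 5.5–7%.
- **Nuisance structure.** Additive Gaussian pixel noise (default sd 3
  gray levels), a lateral illumination gradient (0.01 gray levels per
  pixel), and — with probability `merge_prob` per adjacent pair — a
  merged lane pair. Merging is realized as a thin (~4-row) smear of
  moderate stain joining the two HbA blobs at their migration row, the
  way sample material dragged between application points connects
  neighbouring lanes. This produces a narrow neck between two large
  blobs — precisely the failure mode the two-scale erosion exists to
  cut. (Directly shifting two lanes until their saturated band windows
  overlap does *not* produce such a neck: the contact is then as tall as
  the thresholded bands themselves, ~25 rows, and no small-element
  erosion can split it; the smear model is the geometry under which
  lane-touching is both realistic and recoverable.)
- **Ground truth and determinism.** Per-lane boxes (pairwise disjoint,
  left-to-right), class labels, band centre rows and stain fractions are
  returned with every render. Identical `(spec, seed)` pairs are
  bit-identical; datasets written to disk (PNG strips + CSV manifest) are
  byte-identical on rerun, with per-strip seeds derived from the dataset
  seed by fixed offsets.

What the simulator does **not** model: scanner optics and compression
artifacts, stain batch variation, curved or tilted lanes, band smiling,
within-band texture, or any densitometric calibration linking darkness to
true haemoglobin percentages. Passing tests therefore demonstrate the
correctness and internal consistency of the pipeline — oracle-exact
primitives, leak-free protocol, reproducibility, and recoverability of
lanes and labels under the modelled nuisances — not clinical performance
on scanned strips.

## Numerical choices and degenerate inputs

- Otsu ties → smallest threshold; `which.max` over the 256-candidate scan.
- Erosion uses the fit-inside rule (outside pixels are background), so
  erosion/dilation duality holds exactly on the interior but not on the
  1–2 px frame; tests assert it on the interior.
- Bilinear resampling uses half-pixel centres with clamped (replicated)
  borders everywhere — resize, augmentation warps, Score-CAM upsampling —
  so same-size operations are identities.
- Early stopping counts *consecutive* non-improving epochs against the
  best loss so far (strict improvement, 1e-10 slack); with a flat
  validation loss from epoch 1, training stops at epoch 6.
- All randomness flows from explicit integer seeds: per-strip render
  seeds, per-fold training seeds and per-fold augmentation seeds are
  derived from the caller's seed by fixed offsets.

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen to exercise every code path
with comfortable statistical margins: oracle equivalence on 200 random
images/masks; lane recovery on 100 strips (800 lanes, noise sd 3,
`merge_prob` 0.1) at column-IoU ≥ 0.8; the end-to-end property trains
`tinycnn` under the full five-fold protocol on ~400 well-separated
synthetic lanes (no augmentation — the augmentation arithmetic is checked
separately at the protocol's 189 → 2835) and requires pooled accuracy
≥ 90% plus bit-identical metrics on a seeded rerun.

## Known limitations

- The classifier reads the whole lane crop; it does not quantify HbA2
  percentage by densitometry, and multi-class severity grading is out of
  scope.
- Pretrained backbones are interface-only; published real-data results
  are not reproducible without the (undeposited) patient images.
- Lane boxes are rectangles spanning the strip height; strongly tilted or
  curved lanes would need a geometric model the protocol does not define.
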