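---
title: "Focused augmentation and detector evaluation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focused augmentation and detector evaluation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalaug)
```

## The focused augmentation model

Detection datasets for rib fractures on CT are dominated by intact bone:
non-fracture boxes outnumber fracture boxes, and the fracture signal itself
occupies few, low-contrast pixels. Focused augmentation addresses this by
photometrically perturbing *only* the annotated fracture regions, leaving
everything else bit-identical, so the augmented copies enrich the lesion
appearance without disturbing the anatomy a detector uses as context.

The operator is a two-stage pipeline applied inside the union of
target-class bounding boxes:

1. **Speckle noise.** Each masked pixel becomes
   `clip(I + I·n, 0, 255)` with `n ~ N(0, σ²)` — multiplicative noise, the
   texture characteristic of coherent/low-dose imaging artifacts. The
   multiplicative form makes `I = 0` a fixed point: the dark background
   inside a box darkens nothing further. One noise draw is made per pixel
   *position* and reused across channels, so a grayscale image stored as
   RGB stays channel-consistent.
2. **Gaussian smoothing.** The noisy region is convolved with a normalized
   Gaussian kernel, `I''(x,y) = Σ_{i,j∈[-k,k]} I'(x+i, y+j)·G(i,j)`, with
   `k` the kernel half-width (`kernel_size = 2k + 1`; the canonical example
   is `k = 2` for a 5 × 5 kernel). Smoothing after noising keeps the
   perturbation from degenerating into salt-and-pepper texture; the result
   resembles a genuinely lower-quality acquisition of the same region.

Two structural rules matter as much as the formulas. The noise is applied
*before* the blur, in that order. And the blur reads its neighborhood from
the full noise-applied image while writing only masked pixels: pixels just
outside the box inform the convolution, so there is no seam at the box
edge, yet they are never modified themselves. Overlapping target boxes are
unioned into a single mask and processed once, so a pixel under two boxes
is never noised twice.

Geometry is untouched throughout: the augmented copy's label file is
byte-identical to the original's. The augmented variants are merged with
the originals; with the default of one copy per image the training split
doubles. Validation and test splits are never augmented.

## The conventional baseline

The comparison arm applies whole-image transforms: random rotation in
±30°, brightness/contrast adjustment
(`clip(round(contrast·I + brightness))`), and whole-image Gaussian blur.
Each is applied independently with probability 0.5; if all three draws
decline, one transform (chosen uniformly) is forced so the copy is never a
bit-identical duplicate. The order rotation → photometric → blur is fixed
for reproducibility.

Rotation uses bilinear resampling about the image center at the same
output size, filling out-of-frame samples with 0 (the dark CT background).
Boxes are handled exactly: the four corners are rotated in continuous
pixel coordinates, replaced by their axis-aligned envelope, and clipped to
the frame. The envelope necessarily grows for oblique angles — that is the
standard convention for box-labeled data, since the rotated object is no
longer axis-aligned. Boxes whose clipped area falls below 20 % of the
original area (`min_box_visibility`) are dropped, mirroring the behavior
of mainstream augmentation libraries.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `sigma_speckle` | 0.10 | unitless (fraction of `I`) | ≈10 gray levels of noise at mid intensity: visible texture change without obliterating the defect; not dictated by the source method, so config-exposed |
| `kernel_size` | 5 | pixels | the canonical `k = 2` example |
| `sigma_blur` | 1.0 | pixels | standard choice for a 5 × 5 kernel (±2σ support) |
| `target_classes` | `{1}` | — | fracture regions only; intact-bone boxes are context, not targets |
| `copies_per_image` | 1 | — | doubles the training split, matching the growth of the conventional arm so the two strategies stay comparable |
| `max_rotation_deg` | 30 | degrees | the stated rotation range of the baseline |
| `brightness_delta_range` | ±25 | gray levels | common library default |
| `contrast_factor_range` | 0.8–1.2 | unitless | common library default |
| `min_box_visibility` | 0.2 | fraction | drop boxes mostly rotated out of frame |

## Evaluation engine

Matching is greedy and class-strict: detections are processed in
descending confidence (ties broken by input order, and across images by
sorted image id, so results are reproducible), each matching its best-IoU
unmatched same-class ground truth if that IoU reaches the threshold; every
ground truth matches at most once. IoU is the closed-form axis-aligned
rectangle overlap in continuous normalized coordinates.

Average precision uses the 101-point interpolated envelope: precision and
recall are accumulated over the pooled, confidence-sorted detections, the
envelope `p(r) = max{precision at recall ≥ r}` is evaluated at
`r = 0, 0.01, …, 1`, and AP is its mean. This is the interpolation used by
the tooling family that reports mAP@50 and mAP@50–95; mAP@50–95 averages
AP over the ten IoU thresholds 0.50 : 0.05 : 0.95, and the mAP values are
macro means over classes present in the ground truth.

Scalar per-class precision and recall are reported at the confidence that
maximizes F1 on the IoU-0.50 curve — the operating point detector
frameworks print — with ties broken toward higher confidence. A
fixed-threshold alternative can be derived from the returned curves.
Degenerate-input conventions: a class with ground truth but no detections
scores precision 0, recall 0, AP 0; detections for a class absent from the
ground truth are skipped with a warning (they cannot be scored); an empty
ground-truth collection is an error.

The comparison table renders `100·(v_new − v_old)/v_old` to two decimals
with an explicit sign. Percent changes are computed from full-precision
metric values; recomputing them from already-rounded 3-decimal table
entries can differ in the last digit, which is why published comparison
columns do not always reproduce from their own rounded neighbors.

## Numerical choices

- **Rounding.** All pixel arithmetic is floating point, rounded
  half-away-from-zero to integers at each stage's output, then clipped to
  [0, 255]. Base R's `round()` rounds half to even, which would make
  results depend on tie parity; half-away is the convention of the imaging
  libraries this format interoperates with.
- **Border padding.** The blur uses reflect padding without duplicating
  the edge pixel (the reflect-101 convention). Images are required to be
  at least 8 pixels a side so the fold is well defined for the kernel
  sizes in use.
- **Box → pixel conversion.** `x1 = floor((cx − w/2)·W)`,
  `x2 = ceil((cx + w/2)·W)` (0-based, half-open), clamped to the frame:
  the pixel region always fully covers the continuous box and exceeds it
  by less than one pixel per side. A 1e-7 pixel-scale guard inside the
  floor/ceil keeps boxes that land exactly on pixel boundaries from
  gaining a spurious extra pixel through binary-float slop. A box that
  maps to an empty region is an error rather than a silent drop.
- **Annotation slop.** Boxes overhanging the unit square by ≤1e-6
  (annotation-tool rounding) are clamped on read; larger violations are
  errors.
- **Label dialect.** Space-separated, 6-decimal fixed point, one box per
  line, `\n`-terminated, UTF-8; parse∘write is the identity to 6 decimals.
- **Reproducibility.** Every stochastic operation derives its stream from
  a base seed plus string tokens (image id, copy index) via a polynomial
  hash modulo 2³¹−1, then R's Mersenne-Twister. Per-image derivation makes
  augmentation order-independent: shuffling the training list changes no
  output pixel.
- **Splitting.** Indices are shuffled with the seeded generator and
  sliced; counts are `round(n·f_train)`, `round(n·f_val)`, remainder to
  test — so 2000 items at (0.7, 0.2, 0.1) give exactly (1400, 400, 200).

## What the phantom emulates — and what it does not

The generator emulates the *structure* of the study data: 640 × 640
8-bit images, two classes with non-fracture boxes more prevalent, several
boxes per image, a 70/20/10 split. Visually it is schematic: bright curved
bands (rib cross-sections) over a dark noisy background, with darkened gap
defects as fractures. Defect boxes carry a 2-pixel margin so floor/ceil
pixelization never truncates the defect, and the gap is forced well below
band intensity, giving a guaranteed contrast property the tests verify.

It does **not** emulate Hounsfield-unit physics, 3-D continuity between
slices, soft-tissue texture, imaging artifacts, or the visual subtlety of
real hairline fractures. Consequently, passing tests demonstrate that the
operators, bookkeeping and metrics are correct — region isolation, label
preservation, metric recovery at known operating points — not that focused
augmentation improves a real detector on clinical CT. That question
requires training real models on real data and is outside this package's
scope, as is the training itself: the package prepares datasets and scores
detections, and its simulated detector is a test double with dialed-in
miss/false-positive rates, not a learned model.

The simulated detector keeps true-positive confidences strictly above
false-positive confidences. This makes precision-recall curves
non-degenerate and expected metric values computable in closed form (e.g.
recall at confidence 0 equals one minus the miss rate, up to binomial
error) at the cost of realism — real detectors' score distributions
overlap.

## Problem sizes

The test suite exercises phantoms at 64–128 pixels and datasets of 10–50
images, sizes at which every property (bit-identity outside masks, oracle
equivalence of the convolution against a naive quadruple loop on 32 × 32
images, 1000-instance AP oracle equivalence, ≥500-box recall recovery)
is checked exhaustively in seconds. The acceptance script measures
dataset-level quantities at the full 640-pixel geometry. Operator
correctness is resolution-independent — the operators are pixelwise or
fixed-kernel local — so small-raster verification transfers.

## Known limitations

- JPEG is supported read-only (via EBImage when available); all outputs
  are PNG, since augmented data must round-trip losslessly.
- Rotation's axis-aligned envelope over-covers oblique objects; tightness
  would require polygon or mask annotations, which the label format does
  not carry.
- The evaluation engine scores axis-aligned boxes only; no confusion
  matrices, area-stratified breakdowns, or COCO-JSON ingestion.
- `pr_curve` pools flags over images before the sweep; per-image AP
  variants are not provided.
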