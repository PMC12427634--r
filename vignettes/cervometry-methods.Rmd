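---
title: "Measuring intervertebral and vertebra-to-foramen distances on cervical radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intervertebral and vertebra-to-foramen distances on cervical radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervometry)
```

## The problem and the pipeline

On a lateral cervical-spine radiograph, disc-space height is proxied by the
distance between the inferior endplate midpoint of one vertebral body and
the superior endplate midpoint of the next, and potential nerve compression
is indexed by the distance between a body and its neural foramen.
`cervometry` automates both measurements. The pipeline has five stages, each
an exported function so any stage can be run, replaced or inspected on its
own:

1. standardize and binarize (`binarize_pipeline()`),
2. localize and crop the spine region (`crop_spine()`),
3. detect vertebrae and foramina (a pluggable contract),
4. localize reference points per detection (`reference_points()`),
5. measure distances and assemble a report (`run_pipeline()`).

All coordinates are 0-based with x = column and y = row; boxes and crop
regions are half-open. Distances are reported in pixels: pixel spacing is
deliberately not assumed, and a `mm_per_px` factor in `pipeline_config()`
scales outputs when calibration is available.

## Binarization

The input is resized to 512×512 (bilinear), median-filtered (3×3), then
contrast-enhanced by global histogram equalization followed by CLAHE. All
windowed operators replicate edge pixels at the border; this avoids the
dark frame that zero-padding would introduce, which would corrupt the
row-scan profile used for cropping.

The binary mask is the conjunction of two thresholds:

* an **adaptive mean threshold** — a pixel is foreground iff it exceeds its
  31×31 local mean minus an offset of 5. This follows the usual mean−C
  convention; note its logical consequence that a perfectly flat region is
  foreground (every pixel trivially exceeds its own mean minus 5). Local
  thresholding captures locally bright structure irrespective of the
  illumination level;
* a **global Otsu threshold** — foreground must also reach the intensity
  `t` maximizing the between-class variance (ties broken toward the lowest
  maximizing `t`, making the operator deterministic). This removes the flat
  background that the adaptive rule alone cannot reject.

Defaults (median window 3, CLAHE clip 2.0 with an 8×8 tile grid, block 31,
offset 5) are the conventional choices for 512×512 radiographs; every value
is exposed in `preprocess_config()`, and the HE and CLAHE stages can be
switched off individually. The HE-then-CLAHE order applies the global
redistribution first and local contrast second; both orders are defensible,
which is why the stages are individually switchable. CLAHE maps each
degenerate (single-intensity) tile identically — redistributing clipped
histogram mass on such tiles would fabricate contrast out of nothing.

Two numerical details matter downstream. First, the equalization mapping is
`round((cdf − cdf_min)/(N − cdf_min) · 255)`, and CLAHE builds its per-tile
mappings with the same formula, so CLAHE with one tile and a large clip
limit degenerates exactly to global HE (a tested identity). Second, Otsu's
criterion is evaluated for every threshold with the lowest maximizer
returned, and the exhaustive 256-candidate search is the test oracle.

## Spine cropping

The row-scan algorithm anchors on the topmost row with the *fewest but at
least one* white pixels. Rows with zero white pixels are excluded: the
target is the thinnest section of the anatomy (typically a disc space or
the upper neck), not empty background. From the anchor row the lateral
bounds are the first and last black-to-white transitions, grown along
contiguous white runs, padded by 50 px per side; with disjoint runs the
span from first to last white pixel is used, which robustly covers spinous
processes split off by binarization. Vertical bounds scan the whole padded
column band for foreground rather than only the two exact boundary columns
(those are padding-inflated and typically all-black); the vertical padding
defaults to 50 px, mirroring the stated lateral padding. Padding is clamped
to the image, so the crop region is always valid, and increasing padding
can only grow it.

## Detection and pairing

A detector is any function `f(image, region)` returning a tibble of labeled
boxes with confidences in the frame of `image`. The package ships an
annotation-backed detector (YOLO text labels, class map 0→C2 … 5→C7,
6→FORAMEN, overridable) and a phantom-oracle detector; an external trained
model can be wrapped in the same contract. Duplicate vertebra labels are
resolved by confidence (ties: larger box, then first), foramen detections
are all kept, and levels are paired as adjacent present labels. Each
foramen is assigned to the vertebra with the nearest box center — simple,
deterministic, and correct on phantoms by construction; the assignment rule
is isolated so a y-overlap rule could replace it. Every detected foramen is
measured independently, since nothing restricts a level to one foramen
detection.

## Reference points and distances

Within each detection box, expanded by 10 % per side (detector boxes often
clip the cortical margin that defines the reference point), the structure
is re-segmented: percentile contrast stretch (2nd→0, 98th→255), Gaussian
blur (σ = 1), Otsu binarization, then morphological opening and closing
with a 3×3 cross. The ROI binarization takes pixels *strictly above* the
threshold: with the lowest-maximizer tie-break the threshold bin belongs to
the dark class, and the strict comparison drops the 1–2 px blur halo that
would otherwise cling to the body outline. Foramen ROIs are
intensity-inverted first, because a foramen is a radiolucent opening — its
structure is dark on the radiograph.

The largest 8-connected component is kept (area ties: the component whose
first pixel in row-major order comes first). Corner landmarks are the
foreground pixels extremizing the four diagonal functionals — bottom-left
= argmax(y−x), bottom-right = argmax(y+x), top-left = argmin(y+x),
top-right = argmin(y−x), ties toward smaller y then x — which is robust to
vertebral tilt and exactly testable on rectangles. The lower reference
point lies where the rounded (half-to-even) mid-column of the two bottom
corners meets the lowest white pixel of that column; the upper point is the
mirror construction. If a concave mask leaves the mid-column empty, the
nearest foreground-bearing column is used and flagged. The
vertebra-to-foramen measurement applies the same construction rotated 90°:
the y-midpoint of the left/right corner landmarks intersected with the
facing boundary, taking the vertebra's foramen-facing side and the
foramen's vertebra-facing (medial) side; which side faces which is decided
by the component centroids, and the lateral side can be selected instead.

Distances are the Euclidean norm between the two points. An intervertebral
measurement connects the upper body's lower reference point to the lower
body's upper reference point — two independently constructed points, not a
shared midline.

Reference points sit on integer pixel coordinates, so each distance carries
an irreducible quantization error of roughly half a pixel per endpoint;
on phantoms the observed mean absolute intervertebral error is ~0.8 px.

## The phantom generator

`generate_phantom()` renders what the measurement problem actually needs
from a lateral view: six bright, individually tilted rounded-rectangle
vertebral bodies stacked along a mildly curved (lordotic) axis with known
gaps; one darker posterior ellipse per level as the neural-foramen region;
a soft-tissue column; a smooth illumination gradient; Gaussian and
salt-and-pepper noise. Ground truth — boxes, endplate-midpoint reference
points, foramen centers, all distances, and the exact body mask — is
computed analytically from the pre-noise geometry, giving an oracle
uncontaminated by the renderer's raster.

Defaults and the reasoning behind the ones that were open choices:

* image 512×512; six bodies (C2–C7), widths 85–115 px, heights 42–56 px —
  proportions of a clinical lateral view at this resolution;
* gaps uniform in [5, 25] px; tilts in ±10°; curvature as a quadratic
  x-offset of body centers with 15 px maximum;
* tilts interpolate smoothly between two sampled endpoint angles with
  ±1.5° per-body jitter. Facing endplates across a healthy disc are
  near-parallel; independently sampled tilts would let adjacent bodies
  pinch or interpenetrate at a corner, which real vertebrae cannot do. A
  guard additionally widens a level's spacing if tilted endplates would
  come within 3 px; ground-truth distances are always computed from the
  final geometry;
* intensities: air 40, soft tissue 100, bone 190, foramen 55 (a
  radiolucent opening, darker than the surrounding tissue);
* the soft tissue is a full-height capsule around the spine axis, at full
  intensity on a ±130 px plateau and tapering linearly to the air level at
  ±175 px — tissue thickness goes to zero at the skin line, and the neck
  column fills a clinical lateral view top to bottom;
* the illumination plane (amplitude 20 at bone level) scales the tissue
  signal proportionally and leaves air untouched, as beam-intensity
  variation does;
* noise: Gaussian σ = 6 plus 0.2 % salt-and-pepper.

What the phantom does *not* emulate: trabecular and soft-tissue texture,
osteophytes and other pathology, projection overlap (jaw, shoulders),
scatter, and detector-specific noise. Passing phantom tests therefore
demonstrates the geometric correctness and noise robustness of the
pipeline's constructions, not clinical-grade performance on real
radiographs — the detector stage in particular is exercised by oracle and
annotation backends, not by a trained network.

One limitation discovered while validating the cropping stage is worth
recording: if a large, perfectly flat background region fills much of the
frame, global HE spreads that region's noise across a wide intensity range,
the post-enhancement histogram becomes near-uniform, and Otsu's threshold
degenerates to an intensity median that cuts *through* the background
class, speckling the binary image far from the spine — which misleads the
fewest-white-pixels row scan. Realistic framing (anatomy filling most of
the image) avoids the regime; images that are mostly empty air would need
the enhancement stages switched off (`use_he`/`use_clahe`) for reliable
cropping.

## Evaluation

Detection quality uses greedy confidence-ordered IoU matching (default
threshold 0.5, the mAP50 convention) with per-class precision, recall and
accuracy; true negatives are undefined in detection and fixed at zero, so
the reported "accuracy" equals Tp/(Tp+Fp+Fn). Average precision uses
all-points interpolation (running precision maximum from the right,
integrated over recall), the deterministic staircase limit of the
continuous definition. Rates with zero denominators are `NA`, never zero.
Agreement between two measurement sets is summarized Pearson-style: per
case and kind, plus across-case averages. With only five level pairs per
case, a case whose true distances happen to cluster tightly can show a low
correlation despite sub-pixel measurement error — a small-sample property
of the correlation coefficient, not a measurement failure.

## Problem sizes and determinism

Everything is deterministic given a phantom seed and configuration: the
pipeline itself uses no randomness, ties are broken explicitly everywhere,
and two runs produce byte-identical reports. The test suite checks
operators against independent brute-force oracles on ≥100 random small
instances each, crop containment on 200 phantoms at default noise (plus
100 at zero noise), and distance recovery on 100 phantoms per noise level;
the acceptance script uses the same cohort sizes. These sizes keep the full
suite within a few minutes while leaving the statistical checks
well-powered.
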