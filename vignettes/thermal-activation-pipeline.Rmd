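---
title: "Locating muscle activation in thermal image sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating muscle activation in thermal image sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachytherm)
```

## The problem

During isolated resistance training (arm curls, kick backs, lateral
raises), the contracting muscle dissipates heat that perfuses to the skin
with a delay of tens of seconds to minutes. An infrared camera pointed at
the bare upper arm (brachium) therefore sees a slowly developing, spatially
localized warm spot over the active muscle — biceps brachii, triceps
brachii, or deltoid. `brachytherm` implements the full analysis chain from
raw temperature frames to a four-class activation call, plus a synthetic
session simulator so every stage can be exercised and validated without
recordings of human subjects.

The chain is: **protocol timing** → **frame selection** → **align / smooth
/ segment / crop** → **60 × 20 grid heat maps** → **difference heat maps**
→ **region statistics and tests** → **CNN classification**.

## The simulator

### What it emulates

A session is a sequence of frames `T(x, y, t)` in °C. The scene is a warm
elliptical "arm" on a cool background:

* outside the arm ellipse: ambient temperature (default 25 °C);
* inside: a baseline skin temperature (default 33 °C), plus
* diffuse arm-wide warming: a fraction (default 0.3) of the cumulative
  activation offset, applied everywhere inside the arm — skin over
  non-active muscle also warms, just less;
* a Gaussian hotspot centered on the target muscle whose peak equals the
  cumulative activation offset `Δ(t)`;
* i.i.d. Gaussian sensor noise with σ = 0.05 °C, the thermal sensitivity
  class of research-grade microbolometer cameras.

The temporal model is **piecewise linear**. During an active set the
offset grows at the exercise rate (default 0.13 °C/min); during recovery
it grows at the recovery rate (default 0.47 °C/min) — skin temperature
rises *faster after* exercise than during it, because accumulated muscle
heat perfuses outward once movement stops — until three minutes of
recovery have elapsed, after which a plateau/decay rate (default
−0.02 °C/min) takes over. Passive sessions (0 kg) produce no offset, and
"vague" sessions (no valid localized activation) get the diffuse term but
no hotspot.

Only average per-phase rates are modeled; we deliberately do not fit an
exponential saturation model, since the analysis only consumes frames at
set boundaries where a piecewise-linear model with the right average rates
is indistinguishable from a saturating one.

### Geometry and calibration

The arm is an upright (optionally rotated) ellipse with semi-axes
0.40 × rows and 0.22 × cols by default, giving the tall aspect the 60 × 20
grid expects. Hotspot centers live in normalized ellipse coordinates:
deltoid at the top center, biceps lower-left, triceps lower-right — chosen
to sit inside the heat-map region that carries each muscle's name. The
simulator renders the *raw camera view*: on a right arm the biceps faces
the image's right side, and the alignment step later mirrors it to the
left.

The hotspot width is elliptical, proportional to the arm semi-axes with
factor 0.465. This constant is a calibration, not a free dial: the
target-region mean of the processed heat maps is
`(quadrant mean of the hotspot + diffuse fraction) × Δ(t)`, and 0.465
makes that bracketed gain 1.0 after the discretization and smoothing of
the real pipeline (it was set by numerical integration over the ellipse
geometry and then checked end-to-end on noiseless frames at 128 × 96 and
512 × 640 resolution). With unit gain, `session_rates()` applied to the
S/E heat-map trajectory recovers the configured 0.13 / 0.47 °C/min within
±0.01 °C/min — which is exactly the consistency the rate-recovery tests
assert.

### What it does not emulate

Real arm silhouettes (the ellipse has no elbow or shoulder), motion
between frames, perspiration, exponential heat-transfer dynamics, vascular
anatomy (the cephalic vein makes real biceps heating more visible than
triceps heating), and camera optics. Tests passing on synthetic sessions
therefore validate the *pipeline arithmetic and its statistical behavior*,
not field performance on human recordings.

## Preprocessing decisions

* **Alignment**: right-arm frames are mirrored so the biceps is always on
  the image left; the operation is stateless and involutive.
* **Smoothing**: 3 × 3 moving average (configurable, odd dims), borders by
  edge replication — minimal denoising ahead of global thresholding.
* **Otsu threshold**: classical discrete formulation, 256 uniform bins
  over the frame's min–max range, returning the bin edge that maximizes
  between-class variance. The implementation is checked against an
  exhaustive search over all candidate edges in the tests.
* **Segmentation**: foreground is *above* threshold (skin is warmer than
  the background), largest 8-connected component, holes filled. The order
  is smooth → segment → crop. Manual touch-up is replaced by an optional
  user-supplied mask override; there is no interactive editing.
* Pixel coordinates are row-major with origin at the top-left.

## Heat maps and regions

The arm's division into "20 horizontal and 60 vertical sections" is read
as 20 divisions across the width and 60 down the height: a 60-row × 20-column
grid, matching the tall arm. The ROI bounding box is partitioned into
near-equal rectangles — base size `floor(n/k)` per axis with the remainder
distributed one pixel each to the trailing cells, so cell sizes never
differ by more than one pixel. Each cell is the mean of its masked
(foreground) pixels; cells with less than half their pixels in the mask
are *missing*, and missing-ness propagates through differencing.

Region layout on the grid: upper half = deltoid, lower-left quadrant =
biceps, lower-right quadrant = triceps; region means ignore missing cells.

Difference maps are computed **later − earlier** so that heating is
positive; the conventional pair names ("S1-E3") name the pair, not a
subtraction order. Pair-ranking percentages are floor-rounded integers,
and ties in the per-session argmax break toward the later pair
(E3 > S3 > E2 > S2 > E1).

## Statistics

* Elevation rates are reported half-even rounded at two decimals (raw
  values retained).
* The training-order test is a Kruskal–Wallis rank test (tie-corrected,
  χ² approximation with k − 1 df; an exact permutation p-value is
  available behind `exact = TRUE` for very small groups). The quantity
  tested per session is the (S1-E3) target-region difference — the single
  most informative contrast per session — grouped by training order.
  Complete ties return H = 0 by convention.
* A 10,000-replicate null simulation (3 groups × n = 10) in the acceptance
  tests checks that the χ² approximation rejects at 5 ± 1 % at α = 0.05.

## Classification

* **Dataset**: one labeled map per session × pair for the (S1-E3) and
  (S1-S3) pairs; missing cells imputed to 0 Δ°C, then min–max
  normalization to 0–1 per map (the bump's *location*, not its absolute
  amplitude, carries the class signal). Degenerate maps (mostly-missing
  grid or an undefined region) are excluded with a warning — the quality
  flag that can shrink the nominal count.
* **Split**: `floor(0.1 × N)` random test maps; with 134 maps that is
  121 train / 13 test.
* **Augmentation**: full factorial of rotations {−1°, 0°, 1°} × scales
  {0.9, 1.0, 1.1} × noise {off, on}, then resize to the classifier
  resolution — 18 variants per map, so 121 maps yield 2178 training
  images. The identity scale 1.0 is included in the factorial; this is
  what makes the ×18 arithmetic consistent. The noise variant adds
  Gaussian noise with mean 0.07 on normalized intensities; its standard
  deviation is not pinned by any external constraint and defaults to 0.07
  (configurable).
* **Network**: a small four-block CNN — conv 3 × 3 (8, 16, 32, 32
  channels), ReLU, max-pool 2 × 2 per block, then a linear softmax head —
  trained with Adam (lr 10⁻⁴), batch 16, 50 epochs, cross-entropy loss.
  It trains on one CPU core in minutes and is implemented with
  Rcpp/Armadillo; training is bit-reproducible under the config seed.
  A deep pretrained residual network would be the natural choice with
  real data at scale, but adds nothing on this benchmark and cannot be
  meaningfully pretrained offline.
* **Input resolution**: the augmentation default is 244 × 244 for recipe
  compatibility; the benchmark and tests train at 64 × 64, which loses
  nothing at a 60 × 20 source resolution and keeps training fast.

### Benchmark

The acceptance benchmark simulates 200 sessions (50 per class) with
randomized baseline (32–34 °C), exercise rate (0.10–0.16 °C/min), recovery
rate (0.40–0.54 °C/min) and hotspot position jitter (±0.1 normalized
units within the target region) at noise σ = 0.05 °C, builds 400
difference maps, splits 90/10 and trains the default recipe. The network
reaches 100 % training accuracy and ≥ 90 % (typically 100 %) test
accuracy; chance is 25 %. This is a scaled-down synthetic analog — it
demonstrates that the difference-heat-map representation linearly exposes
the class signal, not that any particular accuracy holds on human data.

## Problem sizes and numerical choices

Tests and the acceptance script simulate at 128 × 96 px frames (the
geometry keeps the arm ROI comfortably above the 60 × 20 grid minimum),
4 s frame spacing, and cohorts of 70 (bookkeeping/ranking), 5 (rate
recovery) and 200 (classification) sessions; these sizes were chosen so
the full suite runs on a single CPU core in minutes while keeping every
statistical check well-powered. Degenerate inputs error loudly rather
than warn: constant frames (no Otsu threshold), empty masks, protocols
with nonpositive rates, recordings shorter than their protocol, manifests
with duplicate timestamps.

## Known limitations

* The simulator's spatial gain calibration is exact for the default
  geometry; strongly different ellipse aspect ratios change the
  quadrant-mean gain and would need recalibration of
  `hotspot_sigma_frac`.
* `vague` is simulated as diffuse-only warming; real "no valid
  activation" sessions are more heterogeneous (posture errors, compound
  activation), so real vague-class difficulty is understated.
* The order test assumes sessions are independent; repeated measures on
  the same subject would call for a mixed model, which is out of scope.
* PNG heat-map exports are visualizations only and are never re-ingested.
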