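---
title: "Correcting uneven illumination in H&E micrographs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting uneven illumination in H&E micrographs: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heshade)
```

## Why LAB, and what is being modeled

An H&E micrograph carries its diagnostic information largely in
chromaticity: hematoxylin renders nuclei bluish, eosin renders cytoplasm
pink to red. Uneven illumination — a misaligned filament or condenser, a
dimming bulb — appears in the CIE LAB decomposition almost entirely as a
spatial trend in the lightness plane L\*, while the a\*/b\* planes stay
stable. That observation drives the whole design: estimate the lighting
trend on L\*, remove it there, and never touch a\* or b\*. Both
`apply_correction()` and `enhance_nuclei()` return the chromaticity planes
bit-identical to their input; this is asserted bitwise in the test suite.

The lighting model is *additive in L\** and, to good approximation on real
slides, *planar*: L\*(x, y) ≈ c − αx − βy on unstained background. The mask
estimator is built so that it is algebraically exact for planar fields and
degrades gracefully (quadratic interpolation) beyond them.

### Color conversions

RGB ↔ XYZ uses fixed 3×3 matrices with **no gamma companding**: 8-bit
values scaled by 1/255 enter the linear map directly. This is a deliberate
departure from sRGB. Two consequences follow:

* The reference white is defined as the row sums of the RGB→XYZ matrix
  (Xn ≈ 0.950456, Yn = 1, Zn ≈ 1.088754), which makes RGB white map to
  exactly L\* = 100, a\* = b\* = 0 — the anchor the whole "white background"
  logic relies on.
* Because the printed matrices are rounded to six decimals, an RGB→LAB→RGB
  round trip is exact only to about 10⁻⁴, i.e. at most one 8-bit count per
  channel. The test suite pins this bound.

The lightness companding function f(t) is t^(1/3) above
t₀ = (6/29)³ ≈ 0.008856 and the tangent line 7.787037·t + 16/116 below,
which removes the infinite slope of the cube root at 0 while keeping value
and slope continuous at t₀. For the inverse transform the package derives
fz = fy − b\*/200 (from fy, not fx): expanding the forward definitions
shows b\* = 200(fy − fz), so this is the only choice under which
inverse∘forward is the identity; the round trip is tested to 10⁻⁹.

## The mask estimator

Four source points C1..C4 on white background anchor the estimate. The
geometry requires that no three be colinear; colinearity is declared when a
triangle area falls below 10⁻⁹ squared pixels. Coordinates are 0-based
(x = column, y = row, origin top-left), matching the points-file format and
keeping the border rectangle at x ∈ [0, W−1], y ∈ [0, H−1].

The estimator is stepwise:

1. each of the six point pairs defines a line, intersected with the border
   rectangle (a pair lying on one border is its own pair of intersections);
   the deficit m = reference − L\* is linearly extrapolated along the line,
   parameterized by signed distance;
2. each border position averages *all* pairwise linear extensions of the
   intersection values collected on that border (pairs at coincident
   positions are skipped — they carry no direction);
3. an interior pixel takes the mean of the two directional interpolations:
   vertically between top(x) and bottom(x), horizontally between left(y)
   and right(y).

Three design choices here were genuinely open and are worth recording:

* **Interior combination.** The two directional interpolations must be
  combined somehow; the arithmetic mean mirrors the averaging convention
  already used on the borders, keeps the estimate symmetric in x/y, and
  preserves exactness on planes. The composite is quadratic in position.
* **Sparse borders.** Depending on where the points sit, a border can
  collect fewer than two distinct intersection points. Such a border is
  filled from a least-squares plane fitted to the four source deficits,
  evaluated along that border — a fallback that coincides with the exact
  answer on planar fields, so it never degrades the case the method is
  designed for.
* **Unweighted pair means.** Pairs could plausibly be weighted by
  separation; nothing in the construction requires it, and the unweighted
  mean keeps step 2 linear in the sampled values. Implemented unweighted.

Two properties are enforced by tests: exactness to 10⁻⁶ at every pixel of a
256×256 grid under a planar field, and agreement to 10⁻⁹ with an
independent brute-force implementation of the same stepwise geometry on 100
random 16×16 instances.

One property deliberately *not* claimed: for four deficits that are not
consistent with any plane, the composite does not in general reproduce the
deficit at the source points themselves (deviations of order 1 L\* unit are
possible). The interpolation condition at the sources is exact precisely on
planar-consistent quadruples, and that is how the suite tests it. Since the
whole premise is a planar lighting field sampled on white background, this
is the intended operating regime, but users who hand-pick points on stained
tissue should not expect interpolation through their picks.

### Applying the mask

The paper-facing description of the correction is "subtracting the mask
from L\*"; what restores background to white is *adding* the deficit, and
that is what is implemented: L\*out = clamp(L\*in + (factor/5)·mask). The
"mask" is understood as a lighting deficit to be removed. The optimization
factor is an integer 1–5; 5 applies the full deficit, lower values scale it
linearly (the simplest monotone mapping consistent with "the larger the
factor, the brighter"). Clamping to [0,100] happens at this application
point and at image write-out only; intermediates are never clamped, to
avoid compounding truncation across stages.

### Automatic point selection

Candidates are pixels with L\* ≥ 90 (white areas on H&E slides stay above
this even under visible shading; stained tissue does not reach it). The
image splits into quadrants at column ⌊W/2⌋ and row ⌊H/2⌋ (boundary pixels
to the right/bottom). Each populated quadrant contributes the candidate
closest to the centroid of its candidates — the centroid is robust to
scattered stray candidates, and distance ties break by row-major scan order
so results are deterministic. An empty quadrant takes the centroid of the
found points mirrored across the image's vertical and horizontal center
lines into it ("symmetric with respect to the XY axis" is read as this
mirror; rounding to the nearest pixel), with its deficit set to the mean of
the found deficits. The selected set must still pass the colinearity check;
a degenerate configuration raises the same classed error as manual input.

## Nuclei enhancement

The unsharp mask runs on L\* with a 3×3 Gaussian kernel, σ = 3 px
(a deliberately wide σ for a 3×3 support: the kernel is nearly flat, so the
"blur" is a local average and detail = L\* − blur stays small and stable).
The detail is added back as L\* + factor·detail, integer factor 1–12, but
**only where b\* < 0** — bluish, hematoxylin-stained pixels — so eosin
regions and background never sharpen. The threshold on |detail| defaults to
0 to include all minor details. Convolution uses replicate-edge padding
(no rim artifacts); "quantized between 0 and 100" is implemented as
floating-point clamping, not integer rounding, to preserve precision when
stages are chained. Enhancement accepts any LAB image: the normal workflow
runs it after illumination correction, but nothing requires that.

## Validation metrics

`channel_stats()` reports mean, unbiased variance and a 256-bin histogram
of one LAB plane; with `display_scale = TRUE` values are first mapped to
the 0–255 convention of common editors (L\*·255/100; a\*, b\* + 128,
clamped), which is the scale on which b\*-channel means like "133.32" are
read in practice. `variance_f_test()` computes F = s₁²/s₂² with (n₁−1,
n₂−1) degrees of freedom and the two-sided p = 2·min(P(F ≤ f), P(F ≥ f)),
capped at 1; equal variances are rejected at α = 0.05 by default. The F CDF
comes from R's `pf` (regularized incomplete beta). Treating pixels as
independent observations is statistically optimistic — neighboring pixels
correlate — so the test is a comparability check between processing
variants, not a calibrated image-level inference; its type-I error under
truly independent samples is verified to sit near the nominal 5%
(2000 null replicates, n = 500 per sample).

## What the phantoms emulate — and what they don't

`generate_phantom()` paints pink elliptical cytoplasm patches
(base RGB (230,150,140), jittered ±10 counts per object to mimic dye-batch
variability) each holding a bluish elliptical nucleus (base (70,85,160))
on a white background, then adds a known field to L\* and converts back to
8-bit RGB. The base colors were chosen so that, across the whole jitter
range, nuclei have b\* < −20, cytoplasm has b\* > 2 (keeping the b\* < 0
gate unambiguous) and cytoplasm L\* stays below 87, safely under the
L\* ≥ 90 selection band. Four 3×3 corner patches are kept paint-free so
every quadrant always retains true white, and object sizes are budgeted so
at least 5% of pixels stay white.

Phantoms capture the features the method depends on — white gaps, bluish
vs. pinkish chromaticity, an additive lightness field — and *not* tissue
texture, focus blur, chromatic illumination effects, sensor noise, or
stain co-localization. Passing the recovery tests therefore demonstrates
the estimator's correctness under its stated model, not robustness to
every real-slide artifact. Field kinds: `uniform` (evenly dim lamp, mask
constant to 10⁻⁶), `planar` (the target regime, recovery tested to
RMSE < 0.5 L\* on white pixels and < 1.0 overall across 20 seeded
phantoms at 96×96 with slopes up to 0.06 L\*/px), and `quadratic` (beyond
the model; required only to reduce the error versus no correction).

## Problem sizes, tolerances, degenerate inputs

* Test/acceptance sizes: 16×16 for oracle comparisons (100 instances),
  96×96 for end-to-end phantom recovery (20 seeds), 256×256 for the
  planar-exactness grid, 2000 replicates for F-test calibration — sizes at
  which every property is measured in seconds on a single core.
* Geometric tolerance 10⁻⁹ (colinearity, coincident positions, border
  membership); corner intersections deduplicate at 10⁻⁷.
* Degenerate inputs raise classed errors (`heshade_error_*`): coincident or
  colinear points, out-of-bounds coordinates, images without any white
  pixel, factors outside 1–5 / 1–12, even kernel sizes, σ ≤ 0, mask/image
  shape mismatches, grayscale inputs.
* The saved mask TIFF stores deficit/reference in 32-bit samples (the
  available TIFF writer clamps to [0,1]); `read_mask()` restores the
  scale. Negative deficits clamp in the file only, never in memory.

## Known limitations

* The additive-planar model cannot represent multiplicative shading or
  vignetting; strongly curved fields are only partially corrected.
* Auto-selection requires genuine white background in at least one
  quadrant; fully stained fields of view need manual points, and points
  placed on stained tissue violate the white-anchor assumption.
* Chromatic illumination problems (color casts varying across the field)
  live in a\*/b\* and are out of scope; only lightness is corrected.
* The no-companding RGB↔LAB pair is self-consistent but not colorimetric
  sRGB; L\*a\*b\* values differ slightly from ICC-managed pipelines.
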