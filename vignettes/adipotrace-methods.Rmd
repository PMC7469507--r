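---
title: "Adipocyte morphometry with adipotrace: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adipocyte morphometry with adipotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipotrace)
```

# The measurement problem

In H&E-stained adipose sections, adipocytes are large, bright lipid
vacuoles separated by thin dark membrane ridges. Morphometry asks for the
cross-sectional area of many such cells, in µm², from a digital image of a
region of interest at known magnification. `adipotrace` provides three
measurement modes with complementary cost/robustness trade-offs — a
semi-automated trace mode (one click per cell), manual polygon hand
tracing, and ellipse approximation — plus the statistics used to compare
them. This vignette records the models behind each mode, every tunable
parameter, the numerical conventions, and the design decisions that were
genuinely open, so that results are reproducible bit-for-bit.

# Trace mode

## The transform

Trace mode requires a transformed image. The transform is exactly three
steps, in this order:

1. **Levels/shadows stretch.** A piecewise-linear remap of intensity $v$:
   $v \le s \mapsto 0$, $v \ge \ell \mapsto 1$, linear in between
   ($s$ = `shadows`, $\ell$ = `lowLevelIn`). Defaults $s = 0.15$,
   $\ell = 0.9$. The semantics of these two controls were an open choice;
   we interpret them as the input endpoints of a contrast stretch, which
   matches their ordering and their purpose — saturating bright lumens
   against dark membranes. The interpretation is configurable only in the
   sense that both endpoints are parameters.
2. **Binarization.** Foreground iff $v \ge$ `binaryThreshold`
   (default 0.8). The comparison is *inclusive* so pixels saturated to
   exactly 1 by the stretch stay foreground; the threshold must lie
   strictly inside (0, 1). Lowering the threshold can only grow the
   foreground (monotonicity), which the tests assert.
3. **Despeckle.** An iterated binary **majority (median) filter** over a
   disc neighborhood: default radius 5 px, 5 passes. Ties (exactly half
   foreground, possible only where the disc is clipped at the image edge)
   resolve to foreground. At edges the neighborhood is the intersection of
   the disc with the image. Radius 0 is the identity. Majority filtering
   removes isolated speckles of up to roughly the disc radius and fills
   comparable pinholes in cell interiors, which is precisely what the
   trace step needs.

All three steps are deterministic, so the whole pipeline is: identical
images and parameters give bit-identical masks.

### A known, quantified limitation: curvature erosion

Iterated majority filtering approximates motion by mean curvature, so a
*convex* foreground boundary recedes slightly with each pass. A lattice
argument makes the effect unavoidable: the axis-extreme pixel of any
rasterized disc has only 36 of its 81 disc-5 neighbors inside the region,
short of the 41-vote majority, so it always flips on the first pass. For
adipocyte-scale cells this is small — on rasterized discs we measure a
deficit of about 0.3 % of area at radius 55 px, 1 % at radius 38 px, and
5 % at radius 25 px after the default 5 passes — but it means trace-mode
areas are a systematically slight *under*-estimate of the true lumen, on
top of the deliberate convention that the traced region is the lumen
interior rather than the membrane. Both effects push in the same
direction and together explain why trace mode reads below a hand trace of
the membrane (a slope just under 1 with a negative intercept when
regressing TM on HT, which is exactly what the acceptance script
computes). Consequently, *exact* pixel-for-pixel recovery of a curved
cell's ground truth through the default transform is not attainable;
recovery is sub-percent at the default cell scale, and the test suite
asserts it at that tolerance.

## Fill and trace

From the seed click, the cell is the **4-connected component** of
foreground pixels containing the seed, found by an explicit-queue flood
fill (never call-stack recursion, so region size is bounded only by
memory). Because a component is a set, every interior click returns the
same region — trace mode's zero run-to-run variance is a structural
property, not a calibration, and the suite checks it exhaustively over
every interior pixel of a small field.

The **interior boundary** is the set of region pixels with a 4-neighbor
outside the region (pixels beyond the image edge count as outside),
ordered by clockwise Moore-neighbor contour following from the
topmost-then-leftmost boundary pixel with Jacob's stopping criterion. The
8-connected walk over a 4-connected region avoids the classic
connectivity paradox. Conventions fixed here:

* **Area = interior pixel count**, boundary pixels included (they are
  foreground). Whether the original interactive tools counted boundary
  pixels is unknowable from their descriptions; counting them is exact
  for a pixel set.
* **Perimeter** = 1 per 4-neighbor step and $\sqrt 2$ per diagonal step
  along the closed contour; a single-pixel region has perimeter 0. On
  thin one-pixel protrusions a contour pixel may appear twice; that is
  correct Moore-tracing behavior.
* **Leak guard.** A membrane gap lets the fill escape the cell. The fill
  aborts with a "leak detected" error once the region exceeds
  `maxAreaPx` (default 25 % of the image area in `measureCellTM()`;
  batch runs expose `maxAreaFrac`). The right response to a leak is to
  measure that cell by hand trace or ellipse instead.
* Regions touching the image border are measured but flagged
  `touches_border`, since their true extent is cropped.

# Manual modes

**Hand trace.** Shoelace area over the implicitly closed vertex cycle;
orientation-, rotation- and translation-invariant (asserted on random
polygons). A duplicated final vertex — the "double-click to finish"
idiom — is dropped. Self-intersecting traces are *accepted with a
warning* and flagged in the output rather than rejected: operators
occasionally cross one vertex pair, and a loud flag serves review better
than a hard failure.

**Ellipse approximation.** $A$ is half the distance between the two
clicked major-axis endpoints; $B$ is the perpendicular semi-minor length
through the midpoint; area $= \pi A B$. $B > A$ is rejected as mislabeled
axes rather than silently swapped (silent swapping would hide a click
error); a relative excess below $10^{-9}$ is clamped, since CSV
round-tripping can perturb the last bit. The off-center semi-minor
variant some tools allow is deliberately not supported: the minor axis
always passes through the major axis midpoint.

# Statistics

* **Calibration**: area(µm²) = area(px) · (µm/px)². Calibration is always
  user-supplied; there is no default magnification.
* **Histograms**: half-open bins $[e_i, e_{i+1})$ with the last bin
  closed, so the maximum is kept; with a bin count instead of edges,
  equal-width bins span the data range. Six bins is the conventional
  presentation for adipocyte size distributions and is the default.
* **Repeatability**: per (cell, method) mean and *sample* standard
  deviation ($n-1$); a single-run group has SD `NA`, never 0. Methods are
  never pooled.
* **Concordance**: OLS of paired per-cell means, $R^2$ = squared Pearson
  correlation (identical to the coefficient of determination for simple
  regression — stated because "correlation coefficient" and "$R^2$" are
  often used loosely). Concordance is directional; the canonical
  orientations are HT–TM, HT–EA, TM–EA with the first method on x.
  Cells missing in one method are dropped with a warning.

The OLS itself is delegated to `stats::lm`/`stats::cor`; the test suite
cross-checks it against an independently hand-solved normal-equations fit
to $10^{-9}$.

# The synthetic generator

`simulateAdipose()` emulates the features of real adipose H&E that the
pipeline must survive, with exact ground truth:

* intensity levels — background ≈ 0.55, lumen ≈ 0.95, membrane ≈ 0.10 —
  chosen once so the default transform parameters separate lumen from
  membrane and background with margin;
* cells placed without overlap by rejection sampling (bounded attempts,
  then a clear packing error);
* defaults describing one measurement session on a region of interest:
  1024×1024 px, **15 cells** (the standard per-sample protocol), base
  radii 38–55 px ≈ areas of 4 500–9 500 µm² at 1 µm/px (the common
  adipocyte size range), 4 px membranes, 30 background speckles, noise
  SD 0.02;
* `irregularity` deforms outlines to star-convex shapes
  $r(\theta) = r_0 (1 + \alpha\, p(\theta))$ with $p$ a random harmonic
  (orders 2–5) normalized to peak at 1 — non-elliptical contours on which
  EA error grows while TM still follows the boundary;
* membrane **gaps** are bright arcs through the membrane. Because the
  background is mid-grey (and binarizes to background), a gap joins the
  lumen to a bright wedge rather than to an unbounded region; leak
  detection is therefore exercised with the area guard set near the cell
  scale, which is also how a user would configure it. In real packed
  tissue a gap opens into the neighboring lumen and the leak is far
  larger;
* speckles are kept clear of cells so the ground truth stays exact.

Reference annotations are derived from the truth: `truthPolygon()` places
polygon vertices on the outline (at the lumen edge, mid-membrane, or outer
membrane edge, with optional radial jitter emulating operator
variability), and `truthAxes()` returns the ellipse an ideal operator
would click (longest diameter through the center, perpendicular
half-diameter). The acceptance script uses 1.5 px vertex jitter for HT and
4 % axis error for EA — chosen once as plausible operator noise, with EA
the noisier method by construction of its two-click protocol.

**What passing tests do and do not show.** The generator's cells are
isolated, star-convex, evenly lit and noise-stationary. Real tissue has
shared membranes, folds, stain gradients, nuclei and crown-like
structures, and non-convex cells; success on the synthetic fields
validates the algorithms and their contracts, not clinical performance on
arbitrary slides. Calibration, likewise, is assumed correct and is never
inferred from the image.

# Problem sizes and runtime choices

The test suite and acceptance script run on fields of 128–1024 px and
5–20 cells with three repeated runs per method — sizes chosen so the full
suite completes in well under a minute while still covering the default
cell scale; the oracle cross-checks use 100 random 64×64 masks (flood
fill vs. label propagation) and 20 random 24×24 masks (despeckle vs.
explicit neighborhood counting), where brute force is exact and fast.

# Conventions summary

* Coordinates are **1-based (row, col)**, row increasing downward, in the
  API *and* in all annotation CSVs — one convention everywhere, matching
  R matrix indexing.
* RGB → gray by Rec. 601 luminance (0.299, 0.587, 0.114); 8/16-bit
  integers divided by their type maximum; multi-page TIFFs use page 1.
* Results CSVs contain no timestamps (per-cell timing goes to `run.log`),
  so identical configurations reproduce byte-identical results; every run
  writes a `run_params.json` sufficient to reproduce it. CSV is the
  canonical table format, PNG the canonical image export.

# Known limitations

* Curvature erosion of the majority despeckle (quantified above) makes
  trace-mode areas a slight underestimate; a fitment factor between TM
  and HT readings, if needed, should be estimated per protocol.
* Holes inside a lumen (e.g. a nucleus rendered dark) are excluded from
  the component by construction; trace mode measures the bright region
  only.
* No automatic seed proposal: fully automated segmentation is explicitly
  out of scope, as is whole-slide pyramid handling and stain
  normalization.
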