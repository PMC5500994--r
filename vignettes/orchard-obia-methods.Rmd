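---
title: "Delineating orchard trees from surface models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating orchard trees from surface models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchardcanopy)
```

## The problem

A digital surface model (DSM) of an orchard — typically photogrammetrically
reconstructed from UAV imagery — records terrain-plus-canopy elevation at a
few centimeters per pixel. Trees appear as local elevation highs, so a single
raster carries enough information to delineate every individual crown and to
measure, per tree, the three geometric features that drive pruning and
harvest management: projected canopy area (m²), tree height (m) and crown
volume (m³). Repeating the measurement before pruning, after pruning and a
year later turns the same machinery into a per-tree change-detection tool:
pruning impact, annual growth and restoration, summarized per pruning
treatment (traditional thinning, adapted thinning with an open centre, and
mechanical topping).

`orchardcanopy` implements that analysis as an object-based image analysis
(OBIA) pipeline in four phases, plus a synthetic-orchard simulator that
provides exact analytic ground truth, since suitable public field data sets
with truth do not exist at this resolution.

## The delineation model

**Phase 1 — chessboard segmentation.** The raster is partitioned into square
tiles of fixed ground size (default 1 m², anchored at the raster origin;
right/bottom edge tiles are truncated). Only the height layer is used;
an optional co-registered RGB orthomosaic is carried for visual QC only.

**Phase 2 — coarse classification.** A tile is a *tree object* iff the
population (divide-by-N) standard deviation of its DSM values strictly
exceeds `sd_threshold_m` (default 0.10 m). Canopy surfaces are rough and
crown edges produce elevation jumps, while bare soil is locally flat, so
height variability alone separates the classes. The strict inequality
matters at the boundary: a tile with SD exactly at the threshold is bare
soil. Population SD is fixed (and documented) so the threshold is
reproducible; nodata pixels are excluded and an all-nodata tile is soil.

**Phase 3 — border refinement.** Tree tiles that share an edge with a
bare-soil tile become *border objects*; their pixels are re-segmented
individually and each is assigned by the nearest class mean:

$$\text{tree} \iff |z - \mu_\text{tree}| < |z - \mu_\text{soil}|$$

with ties to soil. The means are taken over the provisionally
tree-classified and soil-classified pixels inside a circular window centred
on the pixel. Three design choices here were genuinely open and are worth
recording:

* *Window radius* (default 1.0 m). The window should be commensurate with
  the tile size: at larger radii (e.g. 1.5 m) the tree mean is dominated by
  tall interior canopy, the decision boundary rises, and the low outer
  skirt of a crown is trimmed — on a ground-based half-ellipsoid the area
  loss reaches ~7%, violating our own 5% recovery oracle. At 1.0 m both
  class means stay local and errors drop below ~4.5% in the worst case and
  below ~1% for realistic crowns whose canopy base sits at 0.6 m.
* *Adaptive widening.* A window can contain no soil (or no tree) pixels at
  all — e.g. in the narrow corridor between two crowns, where every
  surrounding tile holds a crown edge. Instead of guessing, the radius is
  doubled (up to four times the base) until both classes are seen; only
  then do empty-class fallbacks apply.
* *Iterated borders.* Refining a border tile can expose bare-soil pixels
  deep inside the provisional tree region (the same corridor case). Tree
  tiles adjacent to newly exposed soil become border objects in the next
  pass. Each tile is refined at most once, so assignments are never
  re-eroded; the iteration terminates after a handful of passes.

Two hole-closing steps complete the phase, both expressions of the same
physical fact: a surface model cannot see bare soil strictly inside a
canopy, because crowns are opaque from above. *Before* refinement, bare-soil
tile islands fully enclosed by tree tiles are reclassified as tree — a
perfectly smooth crown top (a flat apex, or the plateau left by a topping
cut) can have within-tile SD below 0.10 m, and leaving such tiles in the
soil class would both hole the crown and poison \(\mu_\text{soil}\) with
canopy-top elevations, eroding the crown from inside. *After* component
labeling, any remaining enclosed pixel-scale holes are joined into their
surrounding tree object — the analogue of joining classified tree objects
into solid single trees. Real photogrammetric DSMs are textured enough that
both cases are rarer than on noiseless synthetics. Components smaller than `min_tree_area_m2` (default 0.5 m²)
are discarded as noise. Crowns that genuinely merge into one component are
reported as one tree and flagged when they claim the same plantation node.

**Phase 4 — per-tree features.** For every labeled tree:

* *ground reference*: mean DSM over bare-soil pixels within a 1 m Euclidean
  buffer of the crown (pixels of any tree excluded), widened in 0.5 m steps
  to at most 3 m; a tree with no soil within 3 m is a "landlocked" error and
  flagged unreliable. The reference is a single per-tree constant — the
  method's stated procedure — even on sloped terrain.
* *height*: maximum DSM over the crown minus the ground reference (a
  `height_quantile` option exists for noisy DSMs; the default is the raw
  maximum).
* *area*: pixel count × pixel area.
* *volume*: \(\sum_{px} a_{px} \max(0, z_{px} - z_\text{ground})\). Negative
  per-pixel heights are clamped so noise on buffer soil cannot subtract
  volume.
* *grid identity*: the centroid is rotated into the plantation frame,
  divided by the 8 m / 4 m spacings and rounded to the nearest node,
  clipped to the grid. Ties for a node keep the nearer centroid; the loser
  is flagged. The treatment follows from the row blocks (rows 1–9 / 10–18 /
  19–27 by default).

## Multi-temporal statistics

Trees are matched across dates on (row, column); only pairs reliable on both
dates enter statistics. For each feature the per-tree percent change is
`100 × (later − earlier)/earlier`, signed. Three comparisons are emitted:
impact (date 2 vs 1), annual growth (date 3 vs 2) and restoration (date 3
vs 1); per tree, `(1 + impact/100)(1 + growth/100) = 1 + restoration/100`
exactly. Treatment summaries report the mean ± sample (N−1) SD of deltas —
population SD is used only for tile classification; the split is deliberate
— and the *mean of per-tree percentages* as the headline percentage.
Whether such tables should be means of ratios or ratios of means is
ambiguous; both are computed (`mean_pct`, `pct_of_means`) with
mean-of-ratios as the headline. Pruning severity is the percent volume
removed over the pruning interval, clipped at 0 and binned into left-closed
classes `[0,10) [10,30) [30,50) [50,∞)` (a severity of exactly 30% falls in
30–50%); annual growth is then summarized per class × treatment.

## The synthetic orchard

The simulator emulates the study conditions: a 27 × 24 plantation grid at
8 × 4 m spacing (648 trees) split into three 9-row treatment sub-plots, on
smooth terrain (a plane plus an optional low-frequency Gaussian field),
rendered at 0.05 m pixels — the same order as centimeter-level UAV ground
sample distances, and a workable compromise between realism and runtime.

Crowns are half-ellipsoids: semi-axis `a` along the row (truncated normal,
mean 1.5 m on [1.35, 1.7]), `b` across rows (mean 2.35 m on [2.05, 2.65]),
apex height mean 4.0 m on [3.6, 4.4], canopy base at 0.6 m, centers
jittered by N(0, 0.05² m²). This yields projected areas of roughly 9.5–13 m²
and heights of 3.6–4.4 m — matching the reported pre-pruning ranges — while
guaranteeing (by the truncation bounds) that 4 m-spaced neighbours never
overlap; an exact ellipse-support check errors out otherwise unless overlap
is explicitly allowed.

Because a DSM sees the canopy *top*, every analytic truth value integrates
the rendered surface, not the botanical solid: for an untruncated
ground-based crown the volume is the classical \((2/3)\pi a b c\); a 0.6 m
canopy base adds the under-rim column; a mechanical topping cut at height
\(T\) uses the exact truncated integral

$$V = \pi a b \left[ r_0^2 T + (r_L^2 - r_0^2) h_b + \tfrac{2}{3} c (u^3 - v^3) \right]$$

with \(u = (T - h_b)/c\), \(r_0^2 = 1 - u^2\), and \(r_L\), \(v\) the
analogous low-cut terms. A test suite cross-checks every closed form against
brute-force numerical integration at 1 cm.

Treatments: *traditional* scales both semi-axes by \(\sqrt{1 - f}\) to
remove volume fraction `f` (default 0.36); *adapted* does the same (default
0.42) and opens a central elliptical core (default 25% of the semi-axes)
down to the ground; *mechanical* draws a per-tree topping height uniformly
on 3.5–4.0 m and applies a 0.7 m low cut. One deliberate convention: a
surface model cannot see an interior gap under an intact canopy, so the gap
is only rendered where it breaches the top; since delineation closes
enclosed holes, the *measured* area includes the gap and truth follows the
same convention, while the gap column contributes zero volume on both sides.

Regrowth scales the horizontal semi-axes (the apex is unchanged — after
pruning these trees grow primarily horizontally) so that volume grows by a
fraction looked up from the tree's own severity class, with unit-mean
lognormal per-tree noise. The defaults — 0.20, 0.35, 0.60, 0.80 for the
four classes — are loosely inspired by reported ranges (lightly pruned
trees growing ~20–40% in a year, heavily pruned ones >75%) but are user
parameters, not calibrated values.

What the simulator does *not* emulate: photogrammetric reconstruction
artifacts (a deletion/spike injector exists, off by default, for robustness
experiments only), crown asymmetry and porosity, cover-crop strips, RGB
texture. Passing tests on these synthetics therefore demonstrate the
correctness of the algorithmic chain under known geometry, not field
accuracy on real UAV products.

## Numerical choices and degenerate inputs

* Tile SDs are computed via the one-pass population formula with nodata
  excluded; an empty tile is bare soil.
* The nearest-mean tie (a pixel exactly midway) goes to bare soil.
* Component labeling is 8-connected (background holes are 4-connected, the
  complement convention).
* A raster with no tree tiles yields an empty mask with zero trees, not an
  error; an empty mask yields an empty record table.
* Crowns >20% nodata, landlocked trees, non-positive heights, off-grid
  centroids and node ties are flagged `unreliable` and excluded from
  matched-pair statistics (mirroring the exclusion of incorrectly
  reconstructed trees from field analyses).
* All randomness flows from explicit integer seeds; fixed seeds give
  byte-identical outputs, which the pipeline manifest records along with
  every parameter value.

## Problem sizes used in the test suite

The full-replica checks run the complete 648-tree field (a ~4400 × 2080 px
DSM) once; recovery and treatment mechanics are exercised on 4 × 5 and
smaller blocks, which behave identically per tree at a fraction of the
cost. Those sizes are the package's validation choices; nothing in the
algorithm depends on them.

## Known limitations

* The ground reference is a per-tree constant; on strongly sloped terrain a
  tall tree's volume mixes slope into the height field (the method's own
  convention, kept deliberately).
* Maximum-based heights are upward-biased under DSM noise (the bias is
  bounded empirically in the tests at <3σ; use `height_quantile` for noisy
  data).
* Touching crowns are reported as a single object; an automatic split is
  out of scope.
* Raster I/O is ESRI ASCII Grid (plain text) plus TIFF for RGB; compressed
  GeoTIFF elevation I/O would require external GIS libraries.
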