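---
title: "Modelling agricultural non-point-source pollution risk and its spatiotemporal evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling agricultural non-point-source pollution risk and its spatiotemporal evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrisk)
```

## The evaluation model

Agricultural non-point-source pollution (AGNPS) — nutrient, pesticide
and livestock-waste loads reaching water bodies through runoff and
percolation — is diffuse by nature, so screening-level risk assessment
works with *pressure indicators* on a raster rather than with source
inventories. `agrisk` implements a three-dimensional multi-factor
evaluation: twelve indicators describe how much pressure enters the
land system (Input: fertilizer, pesticide, livestock), how readily the
landscape translates it towards water (Translate: rainfall erosivity,
relief, soil erodibility, sloping fields, distance to water) and how
the receiving system responds (Output: water quality, water capacity,
water-network density, paddy retention).

Each indicator is the ratio of a cell's raw value to a reference:
`I = C/E` where risk grows with `C` (positive direction) and `I = E/C`
where risk falls with `C` (negative direction: distance to water,
water capacity, network density, paddy retention). The reference
values are fixed domain constants (250 kg/ha fertilizer, 2.5 kg/ha
pesticide, 100 J·cm/(ha·h) erosivity, 50 m relief over a 7×7 window,
15° field slope, 1500 m distance to water, 61.95 runoff modulus,
0.404 km/km² river and 0.025 km²/km² lake density, 0.3339 paddy share
of farmland). The livestock and water-quality indicators have no
scalar reference: their sub-indices are already reference-scaled
ratios and are combined with the Nemerow composite
`P = sqrt((mean^2 + max^2)/2)`, the standard environmental-quality
form that up-weights the worst sub-index. Weighted aggregation uses
the expert (Delphi-elicited) coefficients shown by `coef()` on a
fitted surface; each weight set sums to 1, so the composite is a
convex combination and always lies between the dimension extremes.

The composite `A` is graded on five classes bounded at 0.7, 1.0, 3.0
and 5.0. Boundary conventions are centralised in `grade_scale()`:
intervals are left-open/right-closed except the explicit `<= 0.7` and
`>= 5.0` endpoints, so 0.7 is *no risk*, 3.0 is *medium* and 5.0 is
*extremely high*.

### Numerical choices

* **Cap.** Normalized indices are capped at 10. Negative-direction
  indices diverge as `C -> 0` (a cell inside a river has distance 0),
  and an uncapped index would let a single indicator dominate the
  composite unboundedly. The cap is implemented for negative indices
  by flooring `C` at `E/10` before division, which realises the cap
  exactly; 10 lies safely above the extremely-high-risk cut of 5, so
  capping never reclassifies a cell downwards.
* **Nodata.** A cell missing in any indicator is nodata in the
  composite. Renormalizing the remaining weights would silently change
  the model, so it is never done.
* **Focal windows.** The 7×7 neighbourhood statistic uses truncated
  windows at grid edges (no padding), the common behaviour of GIS
  neighbourhood-statistics tools. The statistic defaults to the
  elevation *range* (relief amplitude), the usual choice for this
  indicator; both window and statistic are configurable because
  alternative conventions exist.
* **Geometry.** All layers of one analysis must share shape, cell
  size and origin exactly; mismatches raise an error rather than
  trigger implicit resampling, which tends to hide unit bugs. Cells
  are row-major from the top-left corner with cell-centre semantics;
  all distances are centre-to-centre.

### Open recipe details

A few spatialization details are not fixed by the model definition and
were decided as follows (all reachable through `build_indicator()`
configuration):

* Slope-based sloping-field risk (`I7`) is the continuous ratio
  slope/15° on farmland (0 elsewhere) rather than a step function at
  15°: the reference defines the scale and a continuous ratio
  preserves within-class variation.
* Soil-erodibility `K` values per land-use class and their reference
  are user configuration (`default_k_table()` supplies typical
  values); regional soil surveys differ too much for a universal
  constant.
* Water-network density (`I11`) combines river and lake density by
  unweighted mean of their reference-scaled components before
  inversion.
* Paddy retention (`I12`) is assigned on paddy cells from the zone's
  paddy share; non-paddy farmland receives the capped (worst) value so
  that low retention reads as risk there. The alternative zone-wide
  assignment is available via `paddy_mode = "zone"`.
* County statistics are spread uniformly over their land-use mask
  ("evenly dispersed" assumption) as per-hectare intensities; a zone
  with a positive total but no eligible cells keeps its cells at 0 and
  is reported in a warning, keeping the dispersal semantics literal.
  Each cell belongs to exactly one zone.

## Transition analysis

Grades of three epochs are encoded cellwise as
`B = 100 g1 + 10 g2 + g3`; the three-digit code is readable directly
(123 = no → low → medium). Codes are classified by the monotone-
trajectory rule: all equal → no-change at that grade; non-decreasing
with at least one strict rise → increase; non-increasing with at least
one strict fall → decline; otherwise fluctuation. This rule makes the
published reading of "123" a risk increase and partitions all 125
possible trajectories (the full table is `transition_codebook()`).
Five no-change subclasses are kept even where the upper grades are
empty in practice. The encoding asserts grades ≤ 9 by construction of
the base-10 digits; it is deliberately not generalised beyond three
epochs.

## Kernel density of at-risk cells

Cells at or above a minimum grade become unit points at their centres.
The density surface uses the quartic (biweight) kernel
`3/(pi h^2) (1 - d^2/h^2)^2` for `d < h` with planar Euclidean
distance — the kernel documented for the standard GIS tool this
reproduces — and is reported in points/km² so magnitudes are
comparable across resolutions. The kernel integrates to one point, so
summed density × cell area recovers the point count (verified within
1% for points ≥ 2h inside the boundary). The bandwidth is a required
setting with default `h = 30` cell widths (900 m at 30 m resolution):
large enough to merge neighbouring at-risk cells into coherent
gathering areas, small enough to keep distinct clusters separate; no
universal bandwidth rule applies to grade masks, so it is deliberately
explicit configuration. The minimum grade defaults to 3 (medium) —
when no cell exceeds the high-risk cut, the medium-grade spots are the
ones worth mapping — and is raised to 4 to map high/extremely-high
cells only.

The surface is zoned into 10 equal intervals of `[0, max]`; class k
covers `((k-1)w, kw]` with `w = max/10`, zero density falls in class
1, and the exact maximum is guarded into class 10 against
floating-point overshoot of `ceiling`. The top class is the
*gathering mask*; its 8-connected components, with centroids and
areas, are the high-risk gathering zones. An all-zero density surface
(no at-risk cells) has no zoning and is reported as an error naming
the cause.

## Getis-Ord Gi\*

The package implements the standard self-inclusive Gi\* statistic: for
unit i with binary weights `w_ij`,

```
z_i = (Σ_j w_ij x_j − X̄ Σ_j w_ij) /
      (S sqrt[(n Σ_j w_ij² − (Σ_j w_ij)²) / (n − 1)])
```

with `X̄` and `S` the global mean and population standard deviation
including unit i. Positive z marks spatial clustering of high values
(hot spots), negative z of low values. Confidence bins use the
conventional 7-digit two-sided normal critical values 1.644854,
1.959964 and 2.575829 (90/95/99%), signed by z; bin 0 is not
significant. The plain confidence classes are the default; a
Benjamini-Hochberg FDR variant is available, which can only demote
bins. A constant field has `S = 0` and is rejected as degenerate; a
unit without neighbours gets an undefined z and is flagged not
significant with a warning.

Weights schemes are queen/rook contiguity and a fixed distance band,
over grid cells or zones (zone adjacency from shared cell edges,
centroid distances for the band), always stored sparsely. The default
analysis unit is the zone (county means of the composite score),
matching how county-scale results are typically rendered; cell-level
analysis is supported and is what the planted-cluster validation
uses, since a 12-zone map gives the zone-level statistic very little
power.

## The synthetic-landscape generator

`generate_scene()` draws complete study regions so the entire pipeline
is testable without external data. It emulates the input inventory of
a regional AGNPS assessment: a smooth DEM (Gaussian-filtered white
noise scaled to 200–1500 m), slope as the central-difference gradient
in degrees, a six-class land-use map obtained by rank-thresholding a
second correlated field (biased towards low/flat terrain for water and
paddy) so target class shares are matched exactly, a Voronoi partition
into counties, and per-zone statistics drawn once per scene.

The default conditions were chosen once as realistic for a humid
mountainous agricultural region and are not tuned per analysis: ~2%
water area; about one-third farmland with paddy roughly a third of it;
zone fertilizer intensities ~N(330, 80) kg/ha — between the 250 kg/ha
ecological-construction reference and typical current application
levels — and pesticide ~N(2.75, 0.7) kg/ha; runoff modulus and
river/lake densities centred exactly on their long-term reference
values (61.95, 0.404, 0.025), which by definition are the regional
averages; water-quality sub-indices lognormal around 1 (at the
standard); livestock ratios uniform on [0, 1.2]. Under these
conditions the composite spans roughly 0.4–2.6, the band reported for
decade-scale assessments of such regions. The grade histogram is
bimodal — non-farmland mostly no-risk, farmland mostly medium — because
the paddy-retention rule assigns the capped value to all non-paddy
farmland; real regions show a larger low-risk share because
within-farmland variation is richer than a zone-uniform statistic can
express. Passing tests therefore certify the machinery (normalization,
aggregation, grading, transition, density, Gi\*) and known-truth
recovery, not distributional realism of any particular region.

Planted clusters are intensive-agriculture patches: land inside the
disc (except water) converts to dry land, and local fertilizer,
pesticide and erosivity surcharges are solved from the model's own
weight chain so the composite inside the disc reaches the target
grade's interval midpoint. Because clusters perturb *inputs*, not the
output score, recovering them exercises the full pipeline. Targets
that the capped inputs cannot reach (e.g. a no-risk target inside such
a patch, since surcharges only add pressure) raise an error. Epoch
series apply per-zone multiplicative drift to fertilizer/pesticide
totals and a cumulative seeded paddy-to-dry-land conversion; the
default drift (factors 1 → 1.21 → 0.82 and 1 → 1.24 → 0.92, half the
paddy lost) mirrors the observed decade dynamics of intensification
followed by partial de-intensification with shrinking paddy area. All
randomness is fixed by the scene seed; generation restores the
caller's RNG state.

## Problem sizes and runtime

The validation suite runs the oracle-equivalence checks (brute-force
double-loop implementations of the focal, distance, kernel-density and
Gi\* operators) on 50 random grids up to 20×20, and the end-to-end
known-truth recovery on a 200×200-cell, 12-zone, three-epoch scene
with one planted high-risk cluster — sizes chosen so the whole suite
completes in well under a minute on one core while the 200×200 scene
(40 000 cells, ≈1 300 at-risk points) is large enough for the
hot-spot and density statistics to behave asymptotically.

## Limitations

* Rainfall erosivity is consumed as an input layer; computing it from
  rainfall records is out of scope, as is estimating soil erodibility
  from surveys.
* Grid I/O covers the ESRI ASCII raster (lossless text round-trip)
  and CSV zone tables; no reprojection or resampling is performed —
  inputs must share one geometry.
* The weights are fixed expert constants; no sensitivity analysis or
  re-elicitation is included.
* The Gi\* implementation is the planar, single-time statistic;
  space-time (emerging hot-spot) variants are not covered.
* Synthetic terrain is statistically plausible but not hydrologically
  routed; distance-to-water uses straight-line distance, as in the
  underlying indicator definition.
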