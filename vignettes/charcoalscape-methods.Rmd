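---
title: "Methods: detecting relic charcoal hearths and mapping forest change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting relic charcoal hearths and mapping forest change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charcoalscape)
```

## The problem

A charcoal kiln operated on a hillslope leaves a relic charcoal hearth
(RCH): a levelled platform, circular or elliptical, 20–170 m² in area,
cut into the slope and bounded by 1–2 m wide lips that are locally steeper
than the surrounding terrain. On a 0.5 m LiDAR terrain model these
platforms are the only features that are simultaneously *flat inside* and
*sharply bounded*, which is the contrast every stage of this package
exploits. Downstream, charcoal fragments recovered from hearth soils
record the species burned centuries ago, and present-day inventory plots
record today's composition; interpolating both to surfaces and relating
plot structure to environmental drivers completes the picture.

## Detection chain

**Slope.** Horn's 3×3 finite-difference gradient, the de facto GIS
standard; the slope is `atan(sqrt(p² + q²))` in degrees. Borders are
handled by edge replication, and a nodata neighbour falls back to the
centre value, so isolated nodata cells do not blank their neighbourhood.

**Morphological closing.** Grayscale dilation followed by erosion of the
slope raster under a disc structuring element. Closing fills low-slope
features *narrower than the element* — micro-terraces, noise pits — while
platforms, which are wider, keep a low-slope core with a cleaner outline.
The disc holds every integer offset within `diameter/2` (the boundary
pixel at exactly the radius is included; a 7 px disc has 37 pixels).
Diameters 5–10 px are sensible for hearth-sized targets; 7 px (3.5 m at
0.5 m cells) is the default, matched to the smallest platforms. Edge
replication avoids an artificial rim at the raster border, and the
operator keeps its algebraic properties (extensive, increasing,
idempotent), which the test suite asserts on random rasters.

**Seeds and region growing.** Seeds are local minima of the closed slope
below a flatness quantile (default 0.10), thinned so no two are closer
than 10 m. Platform interiors are the deepest minima by construction, so
each platform attracts exactly one seed; residual background minima seed
the non-hearth objects the classifier needs as negatives. Growth is a
priority queue over 4-neighbours: the frontier cell closest (in feature
distance) to the running mean of the adjoining region joins first; a
region stops when no frontier cell is within the similarity threshold
(default 5° of closed slope) or when it reaches the area cap (default
340 m², twice the largest expected platform). 4-connectivity rather than
8 prevents diagonal leakage through the one-or-two-cell-wide lips. Ties
are broken by (row, column), making the labelling deterministic; the
priority queue is compiled (Rcpp) since it visits every cell of a
million-cell raster.

**Features and classification.** For every object × layer the thirteen
summary statistics (min, max, range, sum, mean, population variance, sd,
Gini, five percentiles with linear interpolation) plus shape metrics:
pixel-edge perimeter, perimeter/area ratio, circularity `4πA/P²`, and the
analytic same-area circle reference `2√(π/A)`. The Gini coefficient uses
the population (`n²`) denominator, with the `n(n−1)` variant available;
it is left `NA` on layers with negative values (e.g. a position index)
and imputed by training medians before the forest sees it. The classifier
is a `ranger` random forest (500 trees, `floor(sqrt(p))` candidate
features per split, probability output) — validated by *stratified*
fivefold cross-validation, averaging user's, producer's and overall
accuracy and Cohen's kappa over folds, with the pooled confusion matrix
reported alongside. Confusion matrices follow the remote-sensing
convention (reference in rows, predictions in columns), which fixes the
meaning of user's (precision) versus producer's (recall) accuracy.

## Composition change

Charcoal counts (historical) and basal areas (current) are divided by
their row totals, giving per-unit proportions; a merged
indistinguishable class (Larix/Picea) stays its own taxon. Surfaces come
from inverse distance weighting with power 2 over the 50 nearest points
on a 10 m grid — a deliberately conservative, exact interpolator whose
predictions are convex combinations of the data and therefore never leave
the local data range. All taxa of one table are interpolated with the
same neighbour sets and weights, so the surfaces sum to one cell-wise and
a current-minus-historical difference is a valid proportion change in
[−1, 1]. Interpolation accuracy is leave-one-out (the natural choice for
a deterministic interpolator, since there is no model to refit): ME, MAE,
RMSE in proportion units and the R² of predicted versus measured.

Diversity uses the Brillouin index `H = (ln N! − Σ ln nᵢ!)/N`, evaluated
through log-gamma — appropriate for fully censused collections such as
charcoal fragments. Basal area is not a count, so it is discretised at
one individual per 0.1 m²/ha (a configurable scale) before the formula
applies; this is flagged as an interpretation, and the scale matters only
weakly because H depends on relative abundances once N is moderate.

## Redundancy analysis

RDA is PCA of the fitted values of the multivariate regression of the
plot descriptors on the environmental matrix: centre (and by default
standardise) both, project `Ŷ = X(X'X)⁻¹X'Y` via QR, and eigendecompose
`Ŷ'Ŷ/(n−1)`. Responses are standardised by default because the eleven
descriptors mix stems/ha, m²/ha, percent cover and a dimensionless index;
axis shares are reported as percent of the *total* (not constrained)
variance. Site scores are returned both as linear combinations (`lc`) and
weighted averages (`wa`); biplot scores are correlations of predictors
with the `lc` scores. Significance uses raw-row permutation of the
response matrix with the sum of constrained eigenvalues as statistic and
the add-one estimator `p = (1 + #{perm ≥ obs})/(1 + n_perm)`, which never
reports zero; permuting rows jointly with X leaves p invariant. The test
suite checks the eigenvalues against an explicit hat-matrix oracle at
1e-8 and against an independent implementation, and verifies the
permutation test holds its nominal type-I error in 500 null replicates.

## The synthetic landscape

No suitable LiDAR survey with ground truth is freely available at this
scale, so the generator *is* a first-class module. It emulates:

* a planar hillslope ramp (default 25°, the terrain where kilns needed
  platforms at all) plus band-limited noise — white noise smoothed with a
  4 m Gaussian kernel and scaled to 0.35 m standard deviation. The noise
  model is a choice, not an observation: real micro-topography has
  anisotropy, drainage structure and canopy-filtering artefacts that
  plain smoothed noise does not reproduce;
* platforms: ellipses (axis ratio 0.75–1) levelled at their centre
  elevation, blended back into the slope through the lip annulus by a
  linear ramp. Weathering is approximated by a residual tilt of up to
  1.5° and damped micro-relief, keeping interiors under the 3° flatness
  the detector assumes while avoiding implausibly perfect terraces;
* confusers — the non-hearth class a classifier must reject: gullies
  (tapered trenches whose floor keeps the hillslope dip, steep-sided but
  not flat), boulders (convex bumps), terracettes (narrow elongated
  benches that *are* flat but have the wrong shape);
* charcoal assemblages: 2–6 identifiable fragments per hearth,
  multinomial over {Pinus 0.62, Fagus 0.15, Picea 0.08, Larix/Picea
  indistinct 0.13, other 0.02}, with an optional smooth log-odds trend
  along x for change-map experiments;
* forest plots: 267 plots whose 11 descriptors respond linearly (on the
  standardised scale) to 15 environmental variables through a known
  coefficient matrix. The default matrix encodes two ecological
  gradients — a dominant elevation/heat belt and a secondary
  hearth-influence gradient, deliberately decorrelated so they span
  separate ordination axes — plus weaker soil effects, with residual
  noise sd 0.42. Units are restored by an affine map, which leaves
  standardised analyses untouched.

Default sizes mirror a realistic survey: a 600 × 600 m scene at 0.5 m
cells holding 212 platforms and 453 confusers, giving roughly 650–670
segmented objects for training; 125 hearths contribute charcoal; 267
plots enter the ordination. Everything is deterministic in one seed.

What passing tests *do not* show: performance on real LiDAR, where canopy
gaps, erosion, roads and overlapping features violate the generator's
assumptions. The synthetic classifier separates classes essentially
perfectly because the generator's platforms are geometrically clean;
field accuracies will be lower. The suite demonstrates correctness of the
operators and recoverability of known truth, not field-grade skill.

## Numerical choices and conventions

* Rasters are row-major with row 1 northernmost; cell centres at
  `origin + (i − 0.5)·cell`. Coordinates are planar metres; no CRS
  handling, inputs are assumed co-registered.
* Rasters are written as ESRI ASCII grid — a plain-text format that
  round-trips georeferencing exactly and values to the formatting
  precision; vector outputs are GeoJSON; tables are CSV.
* TWI uses single-flow-direction (D8) accumulation with `tan β` floored
  at 0.001; pits and flats keep their accumulated water. TPI uses a disc
  neighbourhood of radius 10 m by default (excluding the centre).
* Heat load defaults to the non-exponential folded-aspect equation
  (`0.339 + 0.808 cos L cos S − 0.196 sin L sin S − 0.482 cos A sin S`);
  the two exponential variants are selectable.
* IDW treats a point within 1e-9 m of a cell centre as coincident and
  returns its value exactly.
* The permutation test requires at least 99 permutations; 9 999–10 000 is
  the publication-grade setting and costs seconds at 267 × 11.
* The pipeline's density denominator is the scene (or forested) area in
  hectares; when forested and total area differ, both are worth
  reporting, and the forested area is the ecologically meaningful one.

## Known limitations

* Segmentation is single-scale; nested or overlapping platforms merge.
* The hearth/non-hearth decision rides on terrain features only; the
  feature schema accepts arbitrary extra rasters (spectral, textural) but
  none are generated synthetically.
* Outline tracing returns the outer ring only; holes in objects are
  dropped in GeoJSON export.
* GeoTIFF is not written natively (no geospatial raster library is
  required by the package); ESRI ASCII is the interchange format.
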