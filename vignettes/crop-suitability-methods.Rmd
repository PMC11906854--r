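---
title: "Methods: AHP weighted-overlay crop suitability mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AHP weighted-overlay crop suitability mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CropSuit)
```

## The problem

CropSuit maps where a crop can be grown well, given co-registered gridded
environmental layers. Nine criteria drive the analysis — elevation, slope,
soil depth, soil drainage, soil texture, soil pH, soil organic carbon (SOC),
rainfall and temperature — each reclassified into suitability subclasses and
combined into a single index by a weighted overlay. The method targets
coastal rice and coconut systems: rice favours low, flat, clayey,
imperfectly drained land with abundant rain; coconut favours deep,
well-drained loams under a warm, wet annual climate.

## The AHP weighting model

Criterion weights come from the Analytic Hierarchy Process. An n x n
pairwise comparison matrix A holds Saaty-scale judgments (1 = equal
importance ... 9 = extreme dominance), with reciprocals below the diagonal.
Weights are the classical column-normalization approximation: divide each
column by its sum and average the rows. The consistency of the judgments is
summarised by

- the consistency vector (A w) / w and its summary lambda_max,
- CI = (lambda_max - n) / (n - 1),
- CR = CI / RI, with RI the tabulated random index for order n,

and a matrix is accepted when CR < 0.1.

Three lambda_max estimators are exposed. The package default, `rowmax`,
reports the maximum of the consistency vector; this mirrors the widespread
spreadsheet AHP workflow (matrix product of A with the approximate weight
vector, then element-wise division by the weights) in which the largest of
the row ratios is read off as the "maximum eigenvalue", and it reproduces
the packaged matrices' published footers to four decimals
(lambda_max = 9.9122 and 9.8274). `rowmean` gives Saaty's mean estimate and
`eigen` the exact principal eigenvalue; for a perfectly consistent matrix
all three equal n. Note that `rowmax` is conservative: it yields the largest
CI of the three, so a matrix it accepts would also be accepted by the
others.

Two tolerances matter. Reciprocity is enforced within 5 % relative error
because published matrices print reciprocals to two decimals (0.13 for 1/8);
and CR is defined as 0 when RI = 0 (orders 1 and 2), matching the
two-subclass temperature scheme. For n > 10 no RI is tabulated and the
caller must supply one.

```{r ahp}
ahpAnalyze(ricePairwiseMatrix())
```

## Classification schemes

Each criterion has a per-crop `ClassificationScheme` mapping layer values to
subclasses, each with an AHP-derived subclass weight; the subclass judgment
matrices themselves are published only as supplementary material, so the
packaged schemes carry their published weights and consistency footers (n,
lambda_max, CI, RI, CR) rather than reconstructing the matrices. Printed
subclass weights are rounded to two decimals, so a scheme's weights are
required to sum to 1 within 0.02.

Interval bins are lower-inclusive and upper-exclusive, with the extreme
bins absorbing their outer boundary (so elevation exactly 100 m falls in
"100-500" and pH exactly 8.5 in "7.5-8.5"). The boundary convention is the
package's own choice; published tables do not state one. A subclass may
span disjoint intervals: the coconut pH scheme groups intervals symmetric
around the 5.0-6.5 optimum (6.5-7.5 with 4.5-5.0, and 7.5-8.5 with
4.0-4.5). The published coconut pH table presents four weighted groups even
though the accompanying text names six classes; the packaged scheme follows
the table. Likewise the rice depth scheme keeps the published equal weights
(0.28) for its two deepest classes.

Out-of-range values fail loudly instead of clamping: the schemes were built
to span an actual study region's observed ranges, and a value outside them
usually signals a unit error.

Soil preprocessing follows standard practice: 0-5 cm and 5-15 cm layers are
combined thickness-weighted ((5 v05 + 10 v515)/15) to a 0-15 cm value, and
texture classes come from sand/silt/clay fractions via the twelve-class
USDA triangle, then collapse to crop-specific groups (rice: clayey / loam /
sandy loam / loamy sand / sand; coconut: loam / "SL, SiC, Si" /
"S, C, LS").

## Climate preparation

Monthly climatologies are cell-wise means of each calendar month across
years. The rice temperature criterion is the June-September growing-season
mean; coconut uses the annual mean; annual rainfall is the sum of the 12
monthly climatological rasters. Coarse climate grids are downscaled by
inverse-distance weighting of the coarse-cell centers: the prediction is
the d^(-p) weighted mean of the k nearest samples (default k = 12,
configurable up to all samples), an exact hit short-circuiting to the
sample value. The power p is chosen by minimizing the leave-one-out RMSE of
the IDW predictor over a bounded interval (default [0.5, 20]) with
one-dimensional bounded minimization; the optimization objective uses the
same predictor as the interpolation itself. The choice of leave-one-out
RMSE as the objective, and of the neighborhood size, are the package's own
design decisions — standard practice for cross-validated IDW tuning.

## Overlay, classification, masking

The suitability index is S = sum_i W_i w_i(cell): criterion weight times
subclass weight, summed over the nine criteria. Missing data in any layer
propagates. The index is classified into four classes by equal intervals of
the *observed* (non-missing) min-max range — S1 (highly suitable) down to N
(not suitable) — with values on an interior break joining the upper class.
Observed-range breaks are used, not the theoretical scheme bounds, because
an observed index range is what an analyst reports and classifies.

The pipeline order is score, classify, then mask: the land-cover constraint
(water, trees, built area, snow/ice are non-cropland; flooded vegetation,
crops, bare ground, rangeland are cropland) recodes masked cells to a
dedicated class while conserving the cell count, so before/after area
tables stay directly comparable. Areas are cells x cellsize^2 / 10^4
hectares, with percentages over non-missing cells.

## Validation

Suitability maps are validated with presence/absence AUROC. Absences are
sampled uniformly over eligible cells — excluding the S1 class
("leaving highly suitable areas") and, by default, masked non-cropland
cells so that pseudo-absences remain on terrain comparable to the mapped
surface; `allowNoncropland = TRUE` restores the literal
everything-but-S1 reading. AUROC uses the Mann-Whitney rank statistic with
midrank ties (all-tied scores give exactly 0.5), and the accuracy bands
follow the conventional reading: above 0.9 very high, 0.7-0.9 high, below
0.7 low.

One calibration subtlety: the S1-exclusion rule deliberately biases
absences toward low-scoring terrain, which is desirable when validating a
real map but makes a *null* comparison against uniform presences sit above
0.5 by construction (about 0.60 on the synthetic landscape). The package's
no-signal calibration therefore draws null absences over the same support
as the uniform presences (no class exclusions); under that matched design
the null AUROC stays within 0.08 of 0.5 across seeds.

## The synthetic landscape

`generateLandscape()` builds a seeded miniature coastal strip so the whole
pipeline runs end-to-end without downloads: by default a 64 x 64 grid of
250 m cells (16 x 16 km). Random fields are smoothed white noise (separable
Gaussian kernel, autocorrelation length 6 cells) — chosen for simplicity
over variogram-based simulation. The DEM blends a smooth field with a
west-to-east coastal gradient, squared to skew mass toward a low coastal
plain, and is rescaled to [-5, 1200] m; slope is the 3 x 3 Horn stencil in
percent rise. Temperature follows a 12-month coastal cycle (annual mean
about 27 degC at sea level) minus a 0.6 degC / 100 m lapse; rainfall has a
125 mm/km coastward gradient over a 600 mm base spread across a monsoonal
monthly profile. Soil pH, SOC and depth are smoothed Gaussian fields
clipped to the scheme domains (pH 3.5-8.5, annual mean temperature capped
at 29 degC); drainage and the 8-class land cover are rank-sliced smooth
fields, hitting their target class proportions exactly while staying
spatially clumped. Sand/silt/clay come from a softmax of three smooth
fields, so fractions always sum to 100.

Occurrence points model opportunistic presence records: cells are drawn
with probability proportional to logistic(a + b z), where z is the
standardized suitability index. The slope b is "per standard deviation of
the index", and the default intercept places the logistic midpoint at the
upper-quartile boundary — so b = 0 gives uniform presences and large b
concentrates all presences in the top index quartile. The default b = 10
is a strong, planted signal: validation recovers it with AUROC > 0.9.

What the generator does *not* emulate: real geography, the empirical
marginal distributions of any soil product, inter-variable dependence
beyond the elevation-temperature lapse and the coastal gradients, or
observation biases of occurrence databases. Passing the synthetic recovery
test shows the machinery is correct and unbiased, not that any real map is
accurate.

## Numerical choices and limitations

- Grids must be exactly co-registered (1e-6 m tolerance); nothing is
  resampled silently.
- Pixels are half-open, [x, x + cs) by (y - cs, y]; a point on a shared
  edge belongs to the eastern/lower cell.
- Equal-interval classification refuses a constant index rather than
  inventing breaks.
- Degenerate IDW inputs (no samples, all-identical locations) and
  single-class ROC inputs are errors, not warnings.
- Grid I/O uses the plain-text ESRI ASCII raster format with a JSON legend
  sidecar for categorical layers; single band, declared nodata.
- Test problem sizes (64 x 64 landscape, 100-matrix property sweeps, 20
  null-validation seeds) keep the full suite in the tens of seconds while
  exercising every code path; they are the package's chosen study
  conditions, documented here so results are reproducible.
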