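---
title: "Grid-based ESV and landscape ecological risk assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based ESV and landscape ecological risk assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esvrisk)
```

## Scope

`esvrisk` implements a complete analysis chain for categorical land-use
rasters of dry-valley basins: equivalent-factor valuation of ecosystem
services (ESV), a landscape ecological risk index (LERI) from landscape
pattern metrics, natural-breaks grading, bivariate spatial autocorrelation
between the two surfaces, driver attribution with the geographical-detector
q statistic, weighted standard deviational ellipses, and CA-Markov land-use
projection. A seeded synthetic landscape generator supplies multi-epoch
basins with known structure, so the whole chain can be exercised and
validated without any external data.

All stages work on a common spatial skeleton: a land-use raster with six
aggregate classes (cultivated, forest, grassland, water, construction,
unused; codes 1–6, `NA` = nodata) and a square evaluation grid laid over it.
Cell (r, c) covers a half-open square, row 1 is the northmost row, and
coordinates are metric (projected CRS). Cells are binned into evaluation
units by the integer part of their centre coordinate divided by the unit
size, so the unit size need not be an integer multiple of the cell size
(1 km units over 30 m cells bin into 33- or 34-cell columns). A unit is
retained when its valid-cell fraction, measured against a full unit's
nominal cell count, reaches `coverage_min` (default 0.5); how
boundary-straddling units are handled is a package convention, made explicit
and configurable because it affects every per-unit statistic.

## Ecosystem service valuation

The value of one dimensionless service equivalent per hectare is one seventh
of the market value of the regional mean grain yield:

> unit value = yield × price / 7.

With the regional inputs used throughout the examples
(5389.86 kg/ha, 2.41 CNY/kg) this gives 1855.65 CNY/ha. Per-unit ESV is the
bilinear form

> ESV = Σ_i Σ_j A_i · S_ij · unit value,

with A_i the class area in the unit and S_ij the per-class, per-service
equivalent. The packaged table (`inst/extdata/equivalent_factors.csv`)
carries representative aggregate values of the widely used China terrestrial
equivalent scale; the cultivated row uses the dryland values (appropriate
for a dry valley, and the paddy water-supply equivalent is negative, which
the package forbids), and forest/grassland are means over the published
sub-types. Because ESV is linear in both areas and the unit value, swapping
in a regional table is safe and all decomposition identities
(`total = Σ by_class = Σ by_service = Σ per-unit`) hold by construction.
Densities are reported in 10⁴ CNY/ha of valid unit area, the conventional
grading unit. Coefficients are held constant across epochs; no deflation or
cross-sensitivity adjustment is applied.

## Landscape ecological risk

For each unit (area A) and each class present in it (area A_i, patch count
n_i), the classic index bundle is computed:

* separation S_i = (A / 2A_i) √(n_i / A)
* fragmentation F_i = n_i / A_i
* dominance T_i = m·L_i + n·P_i with L_i = n_i / Σ_j n_j (relative density),
  P_i = A_i / A (relative coverage), m = 0.6, n = 0.4
* disturbance D_i = a·F_i + b·S_i + c·T_i with a = 0.5, b = 0.3, c = 0.2
* vulnerability V_i: expert ranks unused 6 > water 5 > cultivated 4 >
  grassland 3 > forest 2 > construction 1, normalized by their total (21)
* loss R_i = V_i · D_i

and the unit's risk index is the area-weighted loss
LERI_k = Σ_i (A_i / A) R_i.

Two choices deserve comment. First, patches are counted *within* each unit
(connected components clipped at unit boundaries, 8-connectivity by
default): the area-weighted aggregation and the mapped 1 km surface demand
unit-local composition, and a unit-local A keeps S_i and F_i on a common
km² footing. Second, absolute LERI magnitudes scale with the unit area
(F_i is patches per km²), so comparisons across studies require identical
unit conventions; within this package the values are used for grading,
association and ellipse weighting, all of which are invariant to a common
monotone rescaling of the surface. The index-notation ambiguity in the
source formulation (class-within-unit vs unit-within-class) is resolved the
only dimensionally consistent way: classes i within unit k.

## Grading

Five grades are fit by exact Fisher–Jenks optimal partitioning (a dynamic
programme over prefix sums, O(k·n²)), minimizing within-class squared
deviation. Intervals are half-open with a closed top. The scheme is fit on
the values of all epochs pooled (configurable per-epoch or fixed breaks),
since reported single interval sets spanning several epochs imply a common
scheme. Grade–area transitions between epochs are accounted on unit areas
in km², and proportion deltas are column-sum minus row-sum shares.

## Bivariate spatial association

The global statistic is the conventional row-standardized cross-Moran:
both variables are z-scored with population standard deviations and

> I = (1/n) Σ_i z_x(i) · Σ_j w_ij z_y(j),

which reduces exactly to univariate Moran's I when y = x. A published
variant of the normalization (an outer factor n over (n−1) ΣW) is retained
as `bivariate_moran_literal()`; under row-standardized weights it differs
from the conventional estimator by the factor n/(n−1), and the two are
compared in the tests. The local form I_i = z_x(i) · lag_i(z_y) is tested by
conditional randomization: x is held fixed and y is randomly reassigned
across units (seeded), two-sided pseudo p-values are computed per unit, and
significant units are typed H–H, L–L, L–H or H–L from the signs of z_x and
the lag of z_y (GeoDa-style conventions: queen contiguity, α = 0.05; the
package default of 199 permutations keeps the bundled runs fast, and 999 is
the conventional choice for full-scale analyses). With zero permutations no
inference is made and every unit is NS.

## Standard deviational ellipse

The ellipse of a surface uses unit centroids weighted by the surface values.
The azimuth solves tan θ = (A + √(A² + 4C²)) / 2C with
A = Σw·dx² − Σw·dy², C = Σw·dx·dy (deviations about the weighted centre),
measured clockwise from north in [0°, 180°); axis standard deviations are
the weighted root-mean-square deviations along and across that bearing, and
the area is π·σ_x·σ_y. The first-power weighted formulas are used (the
squared-weight variant that sometimes appears in print is not a stationary
solution of the weighted spread); correctness is asserted against an
independent eigen-decomposition of the weighted covariance matrix. Axes are
reported at one standard deviation — the scale that matches reported
~99 km major axes on a ~268 km basin — with `scale = 2` available.
Oblateness is major/minor; centroid shifts are Euclidean distances in the
projected plane, reported in km with a bearing.

## Geographical detector

The factor detector is q = 1 − SSW/SST with population variances, so
SST = N·σ² holds literally and q is invariant to affine transforms of the
response. Continuous drivers are discretized by natural breaks with L = 5
strata by default (matching the five-grade conventions; quantile binning is
available, and categorical drivers pass through). The interaction detector
evaluates q on the cross-classification and labels the comparison with
q1, q2 and q1+q2 in the standard five categories. Refinement monotonicity
(intersecting stratifications never decreases q) is asserted as a property.

## CA-Markov projection

Quantity and location are separated. The Markov matrix T_ij is fitted as
transition areas normalized by the source-class area (absent classes get
identity rows) and projects class areas as S_{t+n} = S_t·Tⁿ, one step per
inter-epoch interval. Allocation converts cells toward the projected
demands: candidate cells are ranked by 0.7 × suitability + 0.3 ×
Moore-neighborhood density (radius 2) of the target class with a seeded
tie-break, deficits are spread over 10 rounds so the density feedback can
act, sources are never drained below their own demand, and constraint cells
(water by default) never convert. Allocated areas match demands within one
cell per class whenever feasible. Suitability surfaces are weighted means of
min-max-normalized drivers with monotone directions and optional saturation
caps — a preference is flat once a cell is "good enough" (e.g. any valley
cell is equally fit for construction), which leaves the neighborhood term to
decide placement inside the feasible zone. The weights, directions and caps
in `default_suitability()` are declared package conventions; nothing in the
method constrains them, and they are exposed for replacement.

Validation fits on epochs 1→2, predicts epoch 3, and compares Cohen's kappa
against the persistence (no-change) baseline. Note the structural handicap:
the Markov demands are *net* flows, so reciprocal exchanges partially cancel
and a simulated map can at best recover the net component of change;
beating persistence therefore requires placement skill, not just quantity
fit.

## The synthetic landscape

The generator emulates a dry valley: elevation is a V-profile about a
north–south valley axis plus seeded filtered-white-noise terrain, rescaled
to 993–5076 m. Land use is assigned by elevation bands cut at the cumulative
target class fractions (defaults follow the reported basin composition:
forest 63.02%, cultivated 25.25%, grassland 9.11%, the rest small), with
smooth-noise ecotone mixing, a meandering river plus lake patches in the
valley band, and construction grown as clustered blobs near the axis.
Epochs evolve first-order: construction expands by 35% per epoch into
adjacent cultivated cells (doubling over two epochs, as reported for the
real basin), and grassland converts to forest at 10% per epoch against a
0.5% reverse flow (net afforestation with a shrinking grassland belt). Both
change processes advance along class edges — the most-indented candidate
cells flip first — because the basin's documented dynamics (reforestation
programmes, urban sprawl) are spatially contagious; this is also exactly the
regime in which the CA-Markov first-order, neighborhood-driven assumptions
hold by construction. Driver surfaces comprise terrain derivatives (finite
differences), climate analogues (affine in elevation plus smooth noise),
Euclidean distance transforms to the river/road/centre features, population
and GDP decays, and `agri_potential`: a smoothed copy of the per-cell total
service equivalent with 5% noise, *planted* as the dominant correlate of the
ESV surface so that attribution methods have a recoverable ground truth.

What the generator does not emulate: hydrological realism, anisotropic
terrain, multi-nuclei urban systems, class transitions driven by
unobservable shocks, and measurement error in the land-use maps themselves.
Passing the recovery tests therefore shows the estimators work when their
assumptions hold — it does not certify performance on real remote-sensing
data, where classification noise and non-stationary drivers intervene.

## Problem sizes and numerical choices

The packaged study condition is a 120 × 120-cell basin at 30 m (3.6 km
across) with 300 m evaluation units (144 units), the scale at which all
bundled runs, tests and the acceptance script operate; the 1 km unit default
is kept for full-size rasters. Ties in the Jenks programme resolve to the
earliest cut; classification clamps out-of-range values with a warning;
zero-variance responses and all-zero weights are hard errors; collinear
point sets yield a degenerate ellipse flag with minor axis 0; empty strata
merge with a warning; kappa of two identical constant maps is defined as 1.
Every stochastic component (terrain noise, ecotone mixing, patch growth,
permutation nulls, allocation tie-breaks) is governed by one seed, and full
pipeline runs are bit-reproducible under it.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)
bundle <- run_pipeline(cfg)
bundle$summary
```

The summary reports the per-epoch ESV totals and mean LERI, the bivariate
Moran's I per epoch, the top-ranked driver with its q, and the CA-Markov
validation kappa. `scripts/acceptance.R` recomputes the headline quantities
from scratch and writes them as JSON.
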