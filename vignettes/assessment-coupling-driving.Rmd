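---
title: "Assessment, coupling, and driving: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessment, coupling, and driving: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecocoupling)
```

`ecocoupling` implements a three-part analysis of human-environment
interaction on gridded landscapes: (1) *assessment* — an ecosystem health
index (EHI) and a human activity intensity index (HAI) per analysis unit;
(2) *coupling* — spatial-autocorrelation and coupling-coordination analysis
of the two indices; (3) *driving* — machine-learning attribution of the
indices to climatic and socio-economic covariates, including nonlinear
response thresholds. This vignette explains the models, the parameters
that matter, the synthetic data the package is validated on, and the
design decisions taken where conventions diverge in the literature.

## The assessment models

### Ecosystem health (VORS)

EHI follows the vigor-organization-resilience-services framework:

$$\mathrm{EHI} = (\mathrm{EV} \cdot \mathrm{EO} \cdot \mathrm{ER} \cdot
\mathrm{ESI})^{1/4},$$

a geometric mean, so health collapses when any single component does.
All four components live on $[0,1]$ per analysis unit (a square block of
cells; edge length `unit_cells`, default 10).

**Vigor (EV)** is unit-mean net primary productivity (NPP, gC m$^{-2}$
yr$^{-1}$), min-max normalized. Normalization pools *all years*, so a
unit's EV is comparable across time; the cost is that adding a year can
rescale every EV value, which we accept because level-change summaries
require a common scale.

**Organization (EO)** combines six landscape pattern metrics computed on
each unit's land-cover sub-raster: Shannon diversity (SHDI) and evenness
(SHEI), the division index (DIVISION), interspersion-juxtaposition (IJI),
contagion (CONTAG), and area-weighted fractal dimension (FRAC). The
conventions are the FRAGSTATS ones: patch connectivity defaults to
8-neighbor (configurable), perimeters and adjacencies always use the
4-neighborhood, CONTAG double-counts adjacencies and excludes
landscape-boundary edges, IJI is undefined below three classes (recorded
as missing, never zero), single-cell patches take FRAC = 1, and a
single-class landscape takes SHEI = 0 and CONTAG = 100. Each metric is
min-max normalized across all units and years, then combined with
published weights

$$\mathrm{EO} = 0.1499\,\mathrm{SHDI}' + 0.1502\,\mathrm{SHEI}' +
0.1002\,\mathrm{DIVISION}' + 0.2173\,\mathrm{IJI}' +
0.1191\,\mathrm{CONTAG}' + 0.2633\,\mathrm{FRAC}'.$$

These six sub-weights sum to 1, so EO stays on $[0,1]$; this "flat" form
is the default. The source tables also print a nested form,
$\mathrm{EO} = 0.3001\,LC + 0.4366\,LH + 0.2633\,IC$ with $LC$, $LH$,
$IC$ built from the same sub-weights — but the group coefficient 0.3001
equals the *sum* of its sub-weights, so applying both levels re-weights
the metrics and the total weight is no longer 1. We implement both modes
(`eo_mode = "flat"` / `"nested"`) rather than silently correcting either;
a regression test documents their algebraic relationship. Metrics that
are undefined for some units are imputed with the cross-unit median; a
metric undefined (or constant) for *every* unit is pinned to 0.5, i.e.
it contributes its weight but no contrast.

**Resilience (ER)** is an area-weighted mix of per-class resistance and
recovery coefficients:

$$\mathrm{ER} = \sum_i A_i\,(0.4\,C^{\mathrm{resist}}_i +
0.6\,C^{\mathrm{resil}}_i),$$

with the six-class coefficient table (farmland 0.6/0.4, forest 1.0/0.9,
grassland 0.6/0.7, water 0.8/0.8, construction 0.3/0.2, desert 0.2/0.1)
shipped as `resilience_coefficients()` and overridable. We read $A_i$ as
the *within-unit area proportion* rather than absolute area: the
geometric mean in EHI needs commensurate $[0,1]$ components, and
proportions make ER scale-free (range 0.14-0.94 under the default
coefficients). This is the one place where the formula as printed
(absolute areas) would break the index's own range conventions.

**Services (ESI)** is a weighted sum of five normalized service
indicators (carbon storage, food production, environmental quality, soil
retention, water yield). The service layers are *inputs* — biophysical
service models are out of scope — and the weights come from the entropy
weight method by default: with column-share matrix $p_{ij}$, entropy
$e_j = -\frac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}$ and
$w_j = (1-e_j)/\sum_k (1-e_k)$. Zeros are shifted by $\varepsilon =
10^{-6}$ before the share computation, since the entropy is undefined at
$p=0$; a constant indicator then carries (numerically) zero weight, and
if every indicator is constant the weights fall back to equal with a
warning. Fixed literature weights can be supplied instead
(`esi_weighting = "equal"` or explicit weights to `service_index()`).

### Human activity intensity

$$\mathrm{HAI} = (\mathrm{SLUCC}' + \mathrm{PD}' + \mathrm{NTL}')/3,$$

where SLUCC is the land-use disturbance score (ordinal class weights:
construction 10, farmland 7, grassland 3, others 0; area-proportion
weighted per unit), PD is population density and NTL nighttime-light
intensity, each range-normalized across all units and years. The raw
three-component sum lives on $[0,3]$; we divide by 3 so HAI shares the
$[0,1]$ scale of EHI, which the coupling model implicitly assumes. The
rescale is monotone and order-preserving, so level classifications and
every rank-based statistic are unaffected; only the absolute magnitude
of HAI (and hence of $T$ and $D$ below) depends on this declared choice.

## The coupling models

**Global and bivariate Moran's I.** Univariate
$I = \frac{n}{S_0}\,\frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}$ on
row-standardized queen contiguity over the unit lattice (rook and
distance-band schemes available). The bivariate form replaces $z_j$ by
the z-scored second variable and measures whether high HAI units sit
near high (positive) or low (negative) EHI units. Inference is by
seeded random relabeling (999 permutations by default); the one-sided p
toward the observed sign is primary — the scientific claims here are
directional — and a two-sided p is reported alongside. The two are not
interchangeable: a one-sided test *selected by the observed direction*
rejects a true null at twice its nominal level, so calibration checks
and any non-directional use should read `p_two_sided`. The bivariate
null permutes only the second variable, keeping the spatial arrangement
of the first fixed; this is exact under unit exchangeability and, like
every label-permutation test, anticonservative when both variables are
strongly autocorrelated at the unit scale.

**Getis-Ord Gi\*.** The z-form local statistic with the focal unit
included in its own (binary) neighborhood; classes follow the
1.65/1.96/2.58 ladder (90/95/99%). Raw thresholds by default, matching
the common reporting convention; no multiple-testing correction is
applied.

**Coupling coordination degree.** $C = 2\sqrt{ab}/(a+b)$ (defined as 0
when both indices are 0), $T = \alpha a + \beta b$ with
$\alpha=\beta=0.5$, and $D = \sqrt{CT}$, classified into five bands
(severe dissonance $[0,0.2)$ through high coordination $[0.8,1]$;
half-open, top-closed, so each band edge belongs to the upper band).
Source tables print $T$ as the *product* $\alpha\,a\,\beta\,b$; with
$\alpha=\beta=0.5$ that caps $T$ at $ab/4 \le 0.25$ and makes reported
$D$ values above 0.8 unreachable, so the additive convention — the
standard one in the coupling-coordination literature — is the default
and the printed multiplicative form remains available
(`t_mode = "multiplicative"`) rather than being silently corrected.

**Four-quadrant zoning.** Both indices are z-scored and units fall into
quadrants by sign: I high-EHI/high-HAI (coordinated development), II
low/high (ecological management), III low/low (risk prevention), IV
high/low (potential conservation). $z \ge 0$ counts as high, a
deterministic tie-break. Per-zone area shares and mean $D$ are
summarized per year.

## The driving model

Gradient-boosted tree regression (xgboost backend,
`reg:squarederror`) of EHI, HAI or $D$ on unit-level covariates, with a
seeded 70/30 train/test split, grid-search over depth, learning rate,
tree count and L2 penalty by mean cross-validated RMSE (5 folds by
default), and evaluation by $R^2$, RMSE and MAE. Attribution uses exact
TreeSHAP contributions: per unit, the base value plus the per-feature
$\phi$ values reproduce the model prediction (local accuracy), and
importance shares are $\mathrm{mean}\,|\phi_j|$ as a percentage of the
total. A brute-force Shapley enumeration over feature subsets serves as
an independent oracle for small depth-1 ensembles in the test suite.

**Threshold extraction.** Dependence profiles $(x_{ij}, \phi_{ij})$ are
sorted by feature value, smoothed with a rolling median (window
$\max(11, n/50)$ observations), and every sign change of the smoothed
series is reported with the first crossing primary, plus a bootstrap
interval over units. A monotone-signed profile yields an explicit "no
threshold" result. Because SHAP values are centered, the crossing
estimates where a feature's contribution passes its own mean, not where
a structural kink sits: for a response with a slope change at $b$ and a
one-signed slope, the crossing is displaced from $b$ by an amount of
order the feature's spread times the slope asymmetry. On the synthetic
scenario below that displacement is a few percent of the feature range,
which is why recovery is asserted within 10% of the range rather than
exactly.

The attribution ensembles are kept compact (on the order of 100-300
trees). Beyond fit quality, this is a numerical choice: xgboost
accumulates both predictions and TreeSHAP contributions in single
precision, and the discrepancy between `base + sum(phi)` and the model
prediction grows with ensemble size; compact ensembles keep it below
$10^{-6}$ on $[0,1]$-scaled targets, the tolerance the test suite
asserts for local accuracy.

## The synthetic landscapes

All validation runs on generated data; no external rasters are needed.
The generator (`scenario_config()`, `make_scenario()`) emulates the
statistical structure the analysis assumes:

- **Spatially autocorrelated fields** via FFT convolution of white noise
  with a Gaussian kernel (`correlation_range` in cells); exactly
  seedable, periodic boundary.
- **Topography**: smooth relief plus an optional north-high/south-low
  trend; slope from finite differences.
- **Land cover**: cells ranked by a latent-field/elevation score and cut
  at the cumulative requested class shares, walking classes from
  low-ground (construction, farmland) to high-ground (forest). Realized
  shares match requests to within rounding, and construction sits lower
  than forest by construction.
- **NPP**: a sum of configured driver responses — linear, or piecewise
  with a slope change exactly at a configured breakpoint — plus Gaussian
  noise. The default plants a PET response whose slope steepens beyond
  850 mm, the nonlinear threshold the attribution stage is asked to
  recover. Five service layers are distinct noisy monotone transforms of
  NPP, soil moisture and land cover, so entropy weights are
  non-degenerate.
- **Human layers**: population, nighttime lights and GDP on a log scale
  (heavy-tailed when exponentiated), decreasing in elevation, elevated
  near construction, and tied to ecological condition by
  `coupling_strength` — at $-0.8$ (the default scenario) unit-level
  human pressure and NPP correlate below $-0.4$. Across years the human
  layers drift upward multiplicatively (default +20%/year).

Three presets define the study conditions. `"negative_coupling"` is the
default 100 x 100 landscape above. `"piecewise"` is the attribution
scenario: one year, a fine unit lattice (2500 units at `unit_cells = 2`)
and a strong planted PET breakpoint. `"null"` is the no-effect control:
coupling 0, no drift, a *uniform grassland* cover, and a short
correlation range (2 cells against 10-cell units). Two features of the
null preset deserve emphasis. First, land cover must be uniform because
land use otherwise ties the two index families together mechanically —
farmland raises both the disturbance score (HAI) and the food-production
service (EHI) — which is realistic but is precisely a coupling channel,
not a null. Second, the short correlation range makes unit-level values
effectively exchangeable, which is the regime where label-permutation
inference has its nominal size; a "null" built from strongly
autocorrelated fields would fail calibration for reasons that have
nothing to do with coupling.

What the generator does *not* emulate: real class-boundary geometry
(thresholded Gaussian fields are smoother than cadastral land use),
anisotropy, measurement error structure of satellite products, land-use
*change* between years (cover is held fixed; only human intensity
drifts), and any calibration of magnitudes to a real region. Passing
tests therefore demonstrate that the algorithms recover planted
structure under the stated statistical assumptions — not that any
particular real landscape satisfies those assumptions.

## Numerical conventions and degenerate inputs

- Pooled (all-years) min-max normalization throughout; a constant
  indicator normalizes to 0.5 with a warning.
- Unit aggregation drops blocks with more than half their cells masked;
  mode ties break to the smallest class code; edge blocks are retained.
- Level grading uses equal intervals on $[0,1]$ by default (breaks
  computed as $k$-ths so the usual 0.2 steps are exact in binary);
  quantile grading is available.
- Zero-variance inputs raise explicit errors (Moran, Gi*, quadrants,
  vitality, model fitting) rather than returning NaN.
- Every random operation is seeded; pipeline stages derive their seeds
  from the global seed plus a stage offset, so any stage can be re-run
  in isolation and reproduce the monolithic run. Reports serialize to
  JSON deterministically and are hash-comparable.

## Problem sizes

The shipped tests and the acceptance script run, by design, at desk
scale: 8 x 8 landscapes for the metric oracles, 100-2500 analysis units
for spatial statistics and attribution, 20-50 seed replicates for
power/size checks, and 999 permutations for inference. These sizes were
chosen so the full validation suite completes in minutes on one CPU
while leaving each statistical check adequately powered; the
implementation itself is vectorized and handles substantially larger
lattices.

## Known limitations

- The analysis-unit size is a free parameter; no default is claimed to
  match any published study, and results (especially Moran's I and the
  landscape metrics) depend on it — the classic modifiable areal unit
  problem.
- ESI weighting mixes objective (entropy) and literature-fixed
  conventions in the field; we default to entropy and expose the
  alternative, but the choice materially changes ESI.
- Bivariate Moran permutation inference assumes unit exchangeability;
  with strong residual autocorrelation its one-sided p is optimistic.
- SHAP dependence thresholds locate mean-crossings of centered
  contributions, a proxy for — not an estimator of — structural
  breakpoints.
- Raster I/O is the plain-text ESRI ASCII grid; projected GeoTIFF
  workflows should convert on the way in and out.
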