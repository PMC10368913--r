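---
title: "Methods: valuation, fuzzy ecological quality and change analysis"
author: "ecoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: valuation, fuzzy ecological quality and change analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoscape)
```

`ecoscape` quantifies the ecological footprint of land use/land cover
(LULC) change between a "before" and an "after" date. It was built for
settings such as rapid settlement expansion into forest — refugee camp
growth, peri-urban sprawl — where classified maps for two dates exist
and the question is what the conversion cost in ecosystem services and
in overall ecological quality. This vignette describes the models, the
parameters that matter, and the design choices made where the
methodology left them open.

## Benefit-transfer valuation

The valuation follows the benefit-transfer method: each land-cover
class $k$ with area $A_k$ (hectares) carries published per-hectare
value coefficients $VC_{kf}$ (US\$/ha/yr) for each of 16
ecosystem-service functions $f$, and

$$ESV_k = A_k \sum_f VC_{kf}, \qquad
  ESV_f = \sum_k A_k\, VC_{kf}, \qquad
  ESV = \sum_k \sum_f A_k\, VC_{kf}.$$

The default coefficient table (`esvCoefficients()`) maps agriculture,
forest, settlement and water onto the farmland, forest, urban and
wetland biomes of the global benefit-transfer literature; settlement
carries an all-zero column, so built-up land contributes no service
value. Any table in the same delimited layout can replace it
(`readCoefficientTable()`).

Two totalling conventions coexist in published class tables: summing at
full precision, and summing class values already rounded to 2 decimal
places. The report object exposes both (`total` and `total_rounded`);
printed class tables add up exactly under the latter, so displays use
it, while every internal computation keeps full precision. Rounding is
half-up at 2 decimals. Percent changes are always taken against the
*unrounded* earlier-date value, and a zero baseline yields a missing
percent rather than an infinity.

### Sensitivity

Confidence in transferred coefficients is probed with the elasticity
statistic: scale class $k$'s coefficient column by $1+\delta$ (the
customary $\delta = 0.5$), recompute the total, and form

$$CS = \frac{(ESV_j - ESV_i)/ESV_i}{(VC_{jk} - VC_{ik})/VC_{ik}}.$$

Because the valuation is linear, $CS$ reduces analytically to the value
share $ESV_k/ESV$, independent of the size and the sign of $\delta$.
`sensitivityCS()` computes both signs and asserts their agreement to
1e-12 relative — a self-check that the implementation respects the
linear structure — and reports `elastic` only when $CS > 1$. A class
with an all-zero column (settlement) has no defined elasticity and is
reported as `undefined`, never as 0.

## Fuzzy ecological quality

The EQ index overlays seven parameter surfaces: population density,
land surface temperature (LST), land-use carbon flux, and the four
service-group value surfaces (provisioning, regulating, supporting,
cultural) obtained by spreading the coefficient column sums over the
map (`esvSurface()`). Each raw layer is made *fuzzy crisp*: mapped to
$[0,1]$ so that membership near 1 always signals degradation,
regardless of the variable's natural direction.

Membership shapes (`fuzzify()`):

* sigmoid `large`, $\mu(x) = 1/(1+(x/m)^{-s})$ — for variables whose
  *high* values degrade EQ (population, LST, carbon);
* sigmoid `small`, $\mu(x) = 1/(1+(x/m)^{s})$ — for variables whose
  *low* values degrade EQ (the ecosystem-function surfaces);
* `linear_large` / `linear_small` — clamped ramps between two bounds.

The sigmoid midpoint $m$ (membership exactly 0.5) defaults to the
midrange of the layer's valid values and the spread to $s = 5$, a
common GIS default; both are configurable and every defaulted value is
echoed to the log, because no canonical parameterisation exists for
these layers. Sigmoids require strictly positive inputs. In the
orchestrated pipeline the ecosystem-function surfaces are fuzzified
with `linear_small` rather than the sigmoid: settlement cells hold
exactly zero function value, which the sigmoid cannot accept, and the
linear ramp maps them to membership 1 (maximal degradation) without
arbitrary shifting. Covariate layers keep the sigmoid `large` shape;
should a covariate contain non-positive values (population can), the
pipeline shifts the layer positive by the smallest amount and logs the
shift.

Layers are combined cell-wise (`fuzzyGamma()`):

$$\mu = \Big(1-\prod_i(1-\mu_i)\Big)^{\gamma}\Big(\prod_i \mu_i\Big)^{1-\gamma},$$

which interpolates between the fuzzy algebraic product ($\gamma = 0$,
pessimistic) and algebraic sum ($\gamma = 1$, optimistic); the
operating point is $\gamma = 0.9$. The operator is monotone in every
input, symmetric under layer permutation, and bounded by the product
and the sum — properties the test suite asserts on random grids.
`fuzzyAnd()`/`fuzzyOr()` (min/max) are provided for comparison; which
operator "performs best" is a visual judgement in the source
methodology, so model selection here is user-driven.

The EQ surface is sliced into five ordered categories (very good →
very bad) with equal intervals on $[0,1]$ by default — no published
break points exist — with a quantile scheme as an alternative for
display; a value exactly on a break belongs to the upper class.

## Change analysis

`transitionMatrix()` cross-tabulates the jointly valid cells of the
two dates into counts $n_{ij}$ and row-stochastic probabilities
$p_{ij} = n_{ij}/n_{i\cdot}$ — the Markovian description of the
conversion process. Classes absent at the first date get `NA` rows
rather than fabricated zeros. `flowTable()` is the marginal-conserving
decomposition an alluvial plot displays (out-flows sum to first-date
areas, in-flows to second-date areas), and `netChange()` reports
per-class hectare differences and percentage points of the total.
Cells nodata at either date are excluded and counted in a message; the
same chaining applies to classified EQ maps, giving the EQ-transition
heat map and flow table.

## The synthetic landscape generator

No classified scenes ship with the package, so every downstream stage
is exercised on synthetic landscapes whose generating process is known
exactly. The generator's defaults are the package's study conditions,
fixed once:

* class fractions 43.59% forest, 27.25% settlement, 20.44%
  agriculture, 8.72% water (`studyFractions()`), on a 10 m grid;
* an "after" date produced by `applyTransition()` under a
  forest-conversion row (settlement-dominated, with small flows to
  agriculture and water) whose entries reproduce the study
  conditions' net area changes in expectation
  (`defaultTransitionSpec()`);
* class-contrasted covariates (`covariateDefaults()`): settlement
  hotter, denser and higher-emitting than forest. These means are
  *placeholders* — the carbon coefficients of the source methodology
  are not published — and are clearly replaceable configuration;
* 600 reference points with a 5% uniform labelling error, split 80/20
  into 480 training and 120 test points.

Spatial autocorrelation comes from one Gaussian-smoothed random field
per class (kernel width `smoothing = 5` cells); fields are
rank-transformed to uniform scores and additive offsets are calibrated
iteratively until the arg-max assignment lands within
$\max(0.02,\,3/\sqrt{n})$ of the target fractions, ties resolved to
the lowest class code. `frontier` mode converts the class-i cells
nearest to existing class-j cells (Chebyshev distance) up to the exact
per-pair quota, emulating expansion at forest edges; `random` mode
draws each cell independently, which is the binomial sampling model
under which the estimator-recovery tests are stated. All generators
derive their stream from one root seed with fixed per-operation
offsets and restore the caller's RNG state, so runs are reproducible
and adding a generator call never perturbs another's draws.

What the generator does *not* emulate: sensor spectra, classification
error structure correlated in space, topography, seasonal water
dynamics. Passing tests therefore demonstrate the correctness of the
estimators and the pipeline plumbing on a known process, not the
accuracy of any satellite product.

## Accuracy assessment

`confusionMatrix()`, `overallAccuracy()`, `kappaCoefficient()` and
`perClassAccuracy()` implement the standard confusion-matrix metrics,
with $\kappa = (p_o - p_e)/(1 - p_e)$. The degenerate $p_e = 1$ case
errors rather than returning 0; empty marginals give `NA` per-class
accuracies; points with missing labels are dropped and counted.
Published classifier accuracies for real scenes require those scenes,
so validation is by closed form instead: on uniform-error reference
points with balanced classes, OA converges to $1-\varepsilon$ and
$\kappa$ to $(OA - 1/K)/(1 - 1/K)$, each checked within 3 binomial
standard errors, and $\kappa = 1$ holds exactly under perfect
agreement. An independent implementation (`e1071::classAgreement`)
cross-checks $\kappa$ in the tests.

## Rasters and numerical conventions

Grids are row-0-north matrices with square or rectangular cells in
metres, addressed (row, col), origin at the top-left corner; areas are
planar (geodesic area is out of scope). One nodata sentinel per layer;
nodata in *any* overlay input propagates to derived layers. File
exchange uses the ESRI ASCII grid dialect, which round-trips
categorical rasters bit-faithfully and continuous rasters to better
than 1e-6 relative; the dialect requires square cells. Inputs must be
pre-aligned — `assertAligned()` compares every grid field exactly and
names the first offending layer, and nothing in the package resamples.

## Problem sizes

The bundled demo configuration runs a 200 × 200 landscape pair —
large enough for per-class binomial standard errors around 0.004 on
the dominant class while the full pipeline completes in about a
second. The estimator-recovery checks use a 500 × 500 pair (about
109,000 forest cells, per-entry standard errors below 0.0013) and
10,000-point accuracy samples. These sizes were chosen so sampling
noise sits an order of magnitude below every asserted tolerance.

## Worked example

```{r esv}
a2017 <- areaTable(agriculture = 11711.33, forest = 24982.31,
                   settlement = 15614, water = 4999.61)
a2021 <- areaTable(agriculture = 11853.41, forest = 19494.3,
                   settlement = 20339.45, water = 5620.09)
esvReport(a2017, label = "2017")
sensitivityCS(a2017, class = "forest")
```

```{r pipeline, eval = FALSE}
res <- runFull(demoConfig(42), outdir = "ecoscape_demo")
res$eq_transitions
```

## Known limitations

* Valuation is strictly linear benefit transfer: no discounting,
  demand saturation, or spatial heterogeneity within a class.
* The EQ index has no published membership parameterisation; results
  depend on the midpoint/spread (or bounds) choices, which is why the
  pipeline logs every default it fills in.
* The transition matrix is estimated, never projected forward; no
  Markov-chain forecasting or cellular-automata coupling is included.
* GeoTIFF input is not supported; convert to ESRI ASCII grids first.
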