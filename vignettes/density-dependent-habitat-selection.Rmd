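---
title: "Density-dependent habitat selection for territorial animals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-dependent habitat selection for territorial animals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resource selection models contrast habitat at locations an animal used with
habitat at locations that were available to it. For strongly territorial
species the second half of that contrast is not static: every territory that
is settled removes ground from what later settlers can use, so as density
rises the *available* distribution contracts and shifts. If used and
available samples are drawn as though availability were fixed, temporal
changes in selection coefficients confound genuine behavioural change with
mechanical changes in the availability distribution. Writing relative use as
a weighted distribution,

$$ f_u(X) = \frac{w(X)\, f_a(X)}{\int_E w(X) f_a(X)\, dX}, $$

makes the dependence explicit: the selection ratio $f_u/f_a$ can steepen,
flatten, or switch sign purely because $f_a$ moves. The package therefore
rebuilds the availability domain of every pack in every year and fits a
*resource selection probability function* (RSPF): a logit-link model whose
zeros are genuine absences (ground known to be unoccupied), so the fitted
value is a true probability of territory occurrence,

$$ \hat w(X) = \mathrm{logit}^{-1}\!\big(\hat\beta_0 + \hat\beta_1 x_1 + \dots + \hat\beta_k x_k\big). $$

## The estimation pipeline

**Territories.** Annual territory boundaries come from a cascade. A
pack-year with at least 30 telemetry fixes gets a yearly fixed-kernel
utilization distribution (UD) whose 95% volume isopleth is the territory; a
pack-year pooling at least 30 fixes over years $t-1,t,t+1$ gets a
moving-window UD; otherwise the most recent kernel estimate is carried
forward (method A), a UD pooled over all of the pack's telemetry and track
locations is used (method B), or the minimum convex polygon of its track
locations (method C). The bandwidth is a two-stage plug-in selector applied
per coordinate (diagonal bandwidth matrix); a bivariate normal-reference
rule ($h_j = \hat\sigma_j n^{-1/6}$) is available as a fallback. Before any
kernel fit, locations farther from the median centre than the median
distance plus $k\cdot\mathrm{MAD}$ (default $k = 6$) are screened out; the
cited outlier procedure is not fully specified in the source methods, so
this concrete rule is our choice and is exposed as a parameter.

**Density surfaces.** A longitudinal pack-by-year matrix records observed
pack sizes ($\ge 2$; lone animals are not packs), absences (0), and
not-surveyed cells (NA). Interior NA runs flanked by detections are filled
by linear interpolation of the flanking sizes rounded half-up (the
single-year case is the midpoint); runs flanked by an absence, or touching
the ends of the series, resolve to absent. Sizes convert to territory
densities ($1000 \cdot \text{size}/\text{area}$, wolves per 1000 km²);
overlapping territories sum, which conserves animals. The territory-density
raster is then smoothed with a circular moving window whose radius is the
median of an exponential dispersal kernel (rate $1/55$ km$^{-1}$, median
$55\ln 2 \approx 38.12$ km), giving a *regional* density that varies
smoothly in space and time.

**Occupancy uncertainty.** Estimated boundaries are uncertain, so each
year's territory set is perturbed: a plausible area is resampled per pack
from a normal distribution (pack-specific mean and sd when the pack has at
least two kernel-based estimates, population statistics otherwise;
truncated below at 10% of the mean), the polygon is rescaled to that area,
and the union of the rescaled set is rasterized. Averaging 100 binary
replicates yields a per-cell probability of pack occupancy. Convex vertex
polygons are rescaled by a mitered edge offset with the signed offset
distance found by bisection (1% area tolerance); grid-mask polygons
(isopleth territories) are rescaled by an exact similarity transform about
the centroid, because morphological offsetting on a coarse cell mask cannot
hold a 1% area tolerance. Whether rescaling should preserve edge geometry
or shape is not determined by the source description ("expanded or
shrunk"); both implementations preserve area to tolerance and topology.
Each pack draws its replicate areas from its own seeded substream, so
adding a pack never perturbs another pack's draws.

**Availability domains and sampling.** The unused domain of pack $i$ in
year $t$ is a disc of radius equal to the 0.95 dispersal quantile
($-55\ln 0.05 \approx 164.8$ km, i.e. 95% of dispersal distances are under
165 km) about the territory centroid, minus the pack's own territory.
Other occupied ground is admissible only through an *overlap allowance*
(default: the year's measured overlap proportion, since later settlers
increasingly tolerate overlap), and unoccupied ground carries inclusion
weight $1 - P(\text{occupied})$. Used points are drawn uniformly inside the
territory at one per 50 km² (floor, minimum one: a mean 283 km² territory
yields five); unused points at one per 1000 km² of domain area, split into
an allowance fraction drawn from other occupied ground and a spatially
balanced weighted sample of unoccupied ground. "Spatially balanced" is
realized as systematic sampling of cumulative inclusion weights along a
serpentine (boustrophedon) ordering of the domain cells — a 1-D
space-filling tour on which systematic sampling spreads points in space
with probability proportional to weight. The exact algorithm behind the
source's sampling design is not stated; this realization is our choice.

**Standardization.** All covariates, and regional density, are standardized
(population sd) with scalers computed over the pooled sample table — i.e.
variables are centred prior to model fitting, so main effects are
conditioned on the mean observed density. The scaler record is retained so
predictions and empirical summaries can be mapped back to original units.

**The RSPF.** The design table feeds the hierarchical logistic model

$$ Y \sim X\beta + f(t) + f(x, k), $$

with fixed effects including covariate-by-density products, an independent
Gaussian random intercept per biological year $t$, and independent Gaussian
random coefficients per pack $k$ (a diagonal covariance across covariates;
cross-covariate correlations are deliberately not estimated). Estimation
maximizes the Laplace-approximated marginal likelihood (lme4). Coefficient
summaries follow a mean / s.e. / 2.5th / 97.5th / mode schema computed from
the approximate Gaussian posterior; under this approximation the mode
equals the mean, a documented difference from fully Bayesian machinery
where the two can differ. With the random-effect variances constrained to
zero the marginal likelihood degenerates to the ordinary likelihood and the
fit provably equals single-level logistic regression; `fit_rspf(...,
ranef = "zero")` implements that reduction with the package's own Newton
solver, and the test suite compares it against an independent `glm` fit.
Near-separation in the single-level path falls back to a small ridge
penalty with a warning.

**Diagnostics.** Pearson's $r$ between fitted probabilities and the 0/1
response; AUC via the Mann–Whitney rank statistic (the test suite checks it
against brute-force all-pairs concordance); a WAIC-style criterion and a
leave-one-out score via the log conditional predictive ordinate
($\mathrm{CPO}_i$ = harmonic mean of per-draw likelihoods), both computed
from seeded draws of the approximate Gaussian posterior of the fixed
effects conditional on the random-effect modes (default 1000 draws).

**Interpretation tools.** `density_response_curves()` plots
$\mathrm{logit}^{-1}(\mathrm{logit}(p_0) + (\beta_x + \beta_{x\times d}\,d)\,z)$
for a grid of standardized densities $d$, conditioned on a baseline
occurrence probability $p_0 = 0.5$; the density at which a covariate's
effect switches sign is $-\beta_x/\beta_{x\times d}$.
`pack_heterogeneity_test()` splits packs at the 25th/75th percentiles of
their pack-level coefficient (fixed effect plus random deviation) and
compares mean annual pack sizes between the weak- and strong-response
groups with a $t$ test and a Mann–Whitney rank-sum test.

## Variable pre-reduction

Correlated landscape derivatives are thinned before the hierarchical fit by
lasso-penalized logistic regression over a penalty grid, with the penalty
chosen by cross-validated predictive deviance under the one-standard-error
rule (the sparsest model within one CV standard error of the minimum);
candidates with zero coefficients at the chosen penalty are dropped.
Exactly duplicated candidates are resolved before the lasso, since the
penalized solution over a perfectly collinear pair is not unique.

## The synthetic world

Every stage above is exercised against a generator with a known truth:

- **Landscape**: stationary autocorrelated fields built by circular-FFT
  Gaussian smoothing of white noise, scaled to a requested sill;
  `spatial_range` is the lag at which correlation falls to 0.05. Defaults
  provide a winter-prey index (truth weight $+1$), human footprint ($-1$),
  snow depth ($+0.5$) and two pure-noise layers ($0$); the weighted sum is
  the generative suitability surface.
- **Recolonization**: total abundance follows logistic growth (defaults:
  80 animals growing to a carrying capacity of 700 at intrinsic $r=0.25$,
  mean pack size 4 — sizes $2 + \mathrm{Poisson}(2)$, floored at 2);
  abundance divided by mean pack size sets the pack count. New packs settle
  pre-emptively: the territory shape (a random convex polygon with area
  drawn from Normal(283.10, 171.41) km², truncated positive) is drawn
  first, and the highest-suitability admissible centre is chosen, where
  admissibility tracks a scheduled overlap proportion through *exact*
  polygon-intersection scoring of candidate centres. The default schedule
  rises from 2% to 48% across the series. Ideal despotic and ideal
  pre-emptive settlement share this best-site-first implementation. A pack
  keeps its territory for life; sizes fluctuate by a $\pm 1$ random walk
  floored at 2.
- **Telemetry**: weekly fixes (52 per pack-year) for a collared fraction
  (default 0.7) of packs, drawn inside the true polygon with density
  proportional to $\exp(\text{true suitability})$, contracted toward the
  centroid so use concentrates in the interior, plus Gaussian location
  error (sd 0.2 km). The true within-territory use distribution is a
  modelling convenience — no field study informs it — and is flagged as
  such.
- **Track survey**: per pack-year Bernoulli detection (default 1) recording
  the true size; scheduled panel-gap years are recorded not-surveyed for
  all packs; detected territories contribute boundary and interior track
  points (at least three, so an MCP is always feasible).

What the generator does **not** emulate: individual demography (births,
deaths, dispersal trajectories), observation error in pack counts,
territory drift or splits, seasonal range shifts, and non-stationary
landscapes. Passing recovery tests on this world therefore demonstrates
that the estimation machinery is faithful to its own model, not that the
model captures every feature of field data.

## Theory simulations

`simulate_scenario()` draws used and available samples from 1-D Gaussian
families whose means and sds follow linear paths in occupancy, estimates
both densities with a kernel smoother on a shared grid, and forms pointwise
selection ratios (floored availability at $10^{-8}$; flagged regions are
excluded from qualitative checks). The four named presets encode the
qualitative regimes for an important limited habitat (availability
collapses faster than use, so the ratio at high covariate values *grows*
with occupancy), an important abundant habitat (use converges to a stable
availability, so the ratio flattens toward 1), and their substitutable
counterparts. The source figures' exact generating distributions are not
published; only these qualitative outcomes are treated as contract, and the
paths are configuration, not hard-coded behaviour.

## Numerical choices and problem sizes

- Rasters are row-major matrices on kilometre grids; rasters exchange as
  plain-text ESRI ASCII grids and territories as GeoJSON, formats chosen so
  all artifacts stay text. Planar coordinates throughout; the method is
  CRS-agnostic.
- Focal means (covariate windows, density smoothing) use FFT convolution
  with an explicit window-count normalization, so edge cells average over
  their truncated window exactly.
- The isopleth is the smallest union of grid cells, in decreasing density
  order, reaching the volume level; its contained mass can exceed the level
  by at most one cell's mass. UD grids default to 0.5 km cells; regional
  density rasters to 2 km.
- Monte-Carlo sizes in the test and acceptance suites (worlds of 120–160 km
  extent, 5–25 years, carrying capacities of 90–240 animals, 5–25 occupancy
  replicates) are chosen so each property is measured on a few thousand to
  a few tens of thousands of sample rows; the full default world (300 km,
  19 years, K = 700) runs the identical code path, only larger. Properties
  that hinge on spatial replication — notably the requirement that
  pure-noise layers stay non-significant — need the landscape extent to be
  many correlation ranges across (the 160 km worlds give ~28 independent
  patches at the default 30 km range); on very small landscapes a noise
  layer can correlate with the settlement pattern by chance and reach
  nominal significance, which is a property of the data, not the model.
- All randomness flows through explicit integer seeds; identical seeds
  reproduce worlds, samples and rasters bit-identically.

## Known limitations

One behaviour of the sampling design deserves emphasis. The overlap
allowance ties the share of unused points drawn from other occupied
territories to the measured overlap of that year, which rises steeply as
the population saturates. Because occupied ground is, by construction of
pre-emptive settlement, better-than-average habitat, the *available*
sample's mean habitat quality drifts upward late in a recolonization
rather than staying level — visibly so when the true habitat contrast
between territories and matrix is strong, as in the synthetic defaults
here. The robust signature of density dependence is therefore the
*shrinking differential* between used and available means (the used mean
converges toward the available mean as density rises), not flatness of the
available mean itself; empirical systems with weaker habitat contrast can
show an essentially level available mean alongside the declining used
mean. `suitability_trend()` reports both slopes so either pattern is
visible.

- Pack-level random coefficients assume independence across covariates; a
  full covariance would need many packs per covariate to identify.
- WAIC and the CPO-based leave-one-out score use draws of the approximate
  Gaussian posterior conditional on the random-effect modes; they are
  comparative tools, not exact cross-validation.
- The occupancy simulation perturbs territory *area* only, not location —
  a centroid that is badly wrong stays wrong in every replicate.
- Empirical-Bayes-style spatial interpolation of fitted maps is out of
  scope; fitted probabilities are reported at sample points.
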