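---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
what each model assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic world does and does not
emulate, and where the design was genuinely open. It states no empirical
result that the test suite or the acceptance script does not itself compute.

## 1. The synthetic world

Every input is generated, with hidden ground truth returned alongside, so
all downstream claims are testable by recovery rather than by faith.

**Grid.** A regular latitude–longitude grid, default 18 × 36 (10° cells),
standing in for a 0.5° global grid. The grid preserves what the models
actually consume — a latitudinal thermal gradient, tropics at |lat| < 23.5°,
cell areas shrinking poleward — at minute-scale runtimes. *Resolution is a
real limitation*: on a 20° grid the meridional temperature difference
between adjacent rows (~6 °C) exceeds typical thermal-envelope widths, so
warming moves whole rows in and out of tolerance at once and projection
signs become quantization artifacts. The 10° default is the coarsest grid
we found qualitatively faithful; the acceptance script deliberately keeps
it rather than shrinking further.

**EEZs.** Contiguous rectangular blocks of cells (the analysis needs region
membership, not coastline geometry). Default 14 EEZs: group-level contrasts
(tropical vs extra-tropical, below- vs above-median GDP) are means over
member EEZs, and with many fewer jurisdictions their sampling noise
dominates the climate signal. At least one tropical and one mid-latitude
(23.5–55°) extra-tropical EEZ are always placed so both groups exist and
can hold production. Bathymetry is shallow (30–250 m) inside EEZ blocks and
abyssal outside — EEZs are the world's continental shelves.

**Socioeconomics.** GDP per capita is lognormal with a lower location for
tropical EEZs (meanlog log(4500) vs log(24000), sdlog 0.45), reproducing
the real-world coupling between latitude and income that the below-median
income rule relies on. Coastal population trajectories (2010–2100) grow at
0.2–1.5%/yr per EEZ, so some EEZs exceed +50% by 2050; they are generated
directly because the 100-km coastal buffer of the original analysis is a
data-preparation step, not a model.

**Climate forcing.** Annual fields of SST, bottom temperature, net primary
production, salinity, sea-ice fraction and surface currents, plus the
global surface-air-temperature anomaly ΔT vs 1850–1900. Three scenarios:
`strong_mitigation` saturates below 2 °C by 2100, `no_mitigation` exceeds
4 °C by 2100, `climatology` is stationary at the 1971–2000 mean state.
Local ocean warming is `amplification` (0.85) × the anomaly relative to the
climatological reference; per-cell noise is centered within each latitude
row so the zonal-mean gradient is exactly monotone equator-to-pole at every
time step (an invariant the habitat model depends on). NPP responds at
−5%/°C of local warming (no published value; configurable); the sea-ice
edge retreats poleward with warming.

**Species pool.** Nested taxonomy (class > order > family > genus >
species), finfish and invertebrate functional groups, thermal envelopes
anchored to the climatological temperature at each range center (so every
species is viable somewhere at baseline). Warm-edge tolerance margins are
drawn narrow (0.5–2 °C) at low latitudes and widen poleward — the
documented ectotherm safety-margin pattern, and the mechanism behind
differential tropical sensitivity. A "warm-affiliated" pool places 70% of
range centers in |lat| < 20° and 30% at 25–45°; an all-tropical pool would
leave extra-tropical EEZs with no reference-period production and make the
tropics-vs-extra-tropics contrast undefined rather than informative.

**Production histories.** Fisheries catches are right-skewed across
species and concentrated on small pelagics (55% of tonnage), of which 60%
is split into `reduction` end-use records — fishmeal and oil — so reduction
is ~33% of total catches, matching the long-run share of reduction
fisheries in world landings. Mariculture exists only for farmed species and
expands 5%/yr. The catch-size distribution across taxa has no published
form; the skew parameters are free configuration.

## 2. Catch potential (DBEM)

Habitat suitability per cell is the geometric mean of active memberships:
a trapezoidal thermal membership (0 at tolerance bounds, 1 across the
preferred range; SST for pelagic, bottom temperature for demersal species)
and open-water fraction `1 − ice`, masked to zero outside the species'
latitudinal range and where bathymetry cannot host its depth range. The
membership form is a modeling choice — the variables are prescribed, the
functional form is not.

Carrying capacity distributes unfished biomass B0 over cells by share of
`HSI × NPP`. Two normalizations matter:

* the *pure function* normalizes by the same slice's sum, so ΣKC = B0
  exactly (verified to 1e-9 in tests);
* *projections* anchor the normalizer at the climatological reference sum.
  Re-normalizing every year makes total capacity invariant to warming by
  construction and silently deletes the global-decline mechanism; with the
  anchored normalizer, capacity falls when suitability or NPP fall. This
  was the single most consequential open design point in the build.

Dynamics per time step, in order: logistic reaction toward capacity at rate
`r` (exponential decay where capacity is zero) minus catch `F·B`; one extra
diffusion pass of the reaction increment with the larval coefficient
(larval dispersal acts on recruits only); then conservative explicit
diffusion and first-order upwind advection with no-flux domain boundaries.
Transport fluxes across edges adjoining zero-capacity cells are zeroed:
without this, diffusion drains every finite habitat into lethal cells at a
rate comparable to `F` and all stocks collapse exponentially — an artifact
of naive discretization, not dynamics. Colonization of cells that *become*
suitable is unaffected. The scheme is flux-form and conserves total biomass
to rounding (1e-8 over 1,000 steps is an acceptance criterion); the time
step is auto-halved until `dt·D ≤ 0.25`, `dt·D_larval ≤ 0.25` and
`dt·max|u| ≤ 1`, and a direct call violating a bound errors naming it.

Body weight follows a generalized von Bertalanffy update with shape
exponent 3; warming above the preferred maximum lowers the realized
asymptote by 2%/°C (configurable). Weight is tracked as a state diagnostic;
biomass dynamics are not coupled to it.

Spin-up: 100 years unfished under climatological conditions, starting at
10% of capacity; convergence is declared when the final-year per-cell
change is < 0.1%. Projections then run a 20-year *fished* burn-in at
climatology before catch accounting, so the reference period (1991–2010)
sits at the F = M equilibrium rather than on the unfished-to-fished
transient — otherwise the transient masquerades as a climate signal in the
relative changes. MCP is annual `F·B` summed over sub-steps; the MSY
summary (mean of the ten largest annual catches) is reported as a
diagnostic only — how it should interact with the F = M projection is not
specified anywhere, so it does not feed back into the run.

## 3. Mariculture potential (GOMAP surrogate)

Four steps. (1) Farm suitability reuses the envelope machinery, then
filters: bottom depth ≤ 200 m, EEZ membership, ice ≤ 0.5; suitable area per
EEZ sums the areas of cells passing the filters with HSI ≥ 0.5 (the cutoff
is configurable; no published threshold exists). (2) Price forecasting is a
mean-reverting AR(1) point forecast clamped at zero — a deliberately
light-weight surrogate for the published neural-network forecaster, which
specifies a role, not an architecture. (3) Feed formulation: fishmeal
demand = production × FCR (1.5) × inclusion (0.3) × meal-yield (1) for fed
species, zero for bivalves and other unfed groups; the forage-usage
fraction applied to projections is the 2010–2014 mean, held constant, and
aquafeed composition never changes over time. The crude-protein index has
no published formula; we use `supply/(supply + demand)` of feed protein —
bounded in [0, 1], monotone in forage supply at fixed demand, equal to 1
for unfed species — and label it a stand-in in the output. (4) The
empirical production model is a penalized-spline additive regression
(`mgcv::gam`, REML) of observed production on area, price, HSI and the
protein index; constant predictors are dropped with a warning, predictions
are clipped at zero, and near-singular smooth designs (common at desk
scale, where training tables are small and clustered) fall back to the
linear additive fit. Only species–EEZ pairs with nonzero present-day
mariculture are projected.

## 4. Nutrient content and edible portions

Level means are computed on the concentration scale as means-of-means up
the taxonomy: a genus mean is the unweighted mean of its observed species
means, a family mean the unweighted mean of its genus means, and so on to a
pooled grand mean. This is exactly the descending-priority taxonomic
fallback used for invertebrates, applied uniformly. Method-of-moments
variance components (residual, species, genus, family, order, class) are
estimated from the within/between decomposition at each level, clamped at
zero.

Prediction uses the lowest level with data. A species with its own
observations is shrunk toward its nearest observed ancestor with weight
`n/(n + σ²_e/σ²_species)` — predictions therefore stay in the convex hull
of the species mean and the parent mean, and removing a species' own data
moves its prediction exactly to the parent estimate. 95% intervals are
symmetric normal on the concentration scale with variance equal to the sum
of the components below the provenance level plus the sampling variance of
the provenance-level mean, made non-decreasing along the provenance ladder
(cummax), floored at zero by shifting rather than truncating so the width
is preserved. We chose this over a log-scale normal approximation because
the back-transform couples interval width to the level mean and can
*narrow* intervals as provenance coarsens — violating the monotonicity the
rest of the pipeline assumes. A model fitted to a single observation
carries a flagged default interval width instead of a zero-width interval,
so Monte Carlo never receives degenerate inputs. Farmed species inherit
wild values unchanged.

Edible portions ship as group-level (mean, min, max) fractions: finfish
groups (0.33, 0.60, 0.92), bivalves and gastropods — molluscs excluding
cephalopods — centered at 0.28, crustaceans at 0.56, cephalopods at 0.70.
The finfish mean and all group min/max values beyond the anchors are fixed
once at field-plausible yields and are configuration, not estimates.

## 5. Availability and uncertainty

Availability is `tonnes live weight × edible fraction × concentration`,
with mg/100 g converting at 1e-5 t of nutrient per t edible and g/100 g
(omega-3, protein) at 1e-2. Reduction-flagged records contribute nothing
when exclusion is on; the identity *(excluded) + (reduction-only) =
(unexcluded)* is exact and tested. Projections multiply each species ×
sector × EEZ reference-period mean production by `1 + relative change` in
MCP/MPP (reference 1991–2010); species–EEZ pairs with zero reference
potential are excluded with a diagnostic (their relative change is
undefined), as are projected species absent from the baseline.

Monte Carlo (default N = 1,000): each draw samples one concentration per
species × nutrient from a truncated-at-zero normal parameterized by the
profile's mean and 95% interval (σ = width/3.92), and one edible portion
per functional group uniform on [min, max]; sampled values are held fixed
across all years within a draw (perfect within-draw correlation — whether
the original analysis resampled per year is unstated; holding values fixed
maximizes band realism for trends, and is our documented choice). The
envelope is the pointwise median and 2.5/97.5 percentiles; baselines for
relative results use the reference-period median.

## 6. Trends, scaling, disparities

Historical trends: OLS of availability (normalized to the window-start
value, so the slope reads in fraction/yr) on year; the 1990-style segment
boundary is user-supplied, never estimated. Warming scaling: OLS of %
change (relative to each run's year-2000 value; configurable baseline) on
ΔT, pooling scenarios and years unweighted — whether points should be
weighted by model or scenario is unstated, so the simplest pooling is used
and reported with slope, intercept, s.e., p and n. p-values come from the
OLS t statistic with no autocorrelation correction; with serially
correlated annual points they are optimistic, which is a documented
limitation, not a bug. Disparity tables report % change at horizon years
for tropical vs extra-tropical EEZs (23.5° centroid rule) and below- vs
above-median GDP per capita (ties to the lower group), per nutrient plus
the unweighted mean across the four nutrients.

## 7. What a green suite does and does not establish

The generators emulate *statistical structure*: warming ramps per
scenario, a monotone zonal thermal gradient, taxonomic nesting with
missing nutrient data, skewed catch-size distributions, a ~33% reduction
share, latitude-coupled income. They do not emulate real coastline
geometry, ENSO-scale variability, density-dependent habitat choice,
multi-species interactions, trade, or any particular year's observed
values. Green tests therefore establish that the *mechanisms* are
implemented correctly (conservation, equilibria, analytic catch limits,
recovery of injected truths) and that the *orderings* the science predicts
(no-mitigation worse than strong mitigation; tropics worse than
extra-tropics; lower-income at least as exposed as the global mean) emerge
from those mechanisms — not that any real-world magnitude is reproduced.
Headline magnitudes from the original global analysis are used only as
simulation fixtures in tests, never as targets.

Known limitations, in one place: single-CPU explicit transport limits grid
resolution; no longitude wrap (closed domain); body size does not feed
back into biomass; oxygen and acidification are generated optionally but
unused; the income and tropics groups coincide often in the synthetic
world, so their contrasts are correlated; and at 16–30 species the
species-composition noise in small EEZ groups remains visible in any
single run — group contrasts are robust in sign across seeds, not in
magnitude.
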