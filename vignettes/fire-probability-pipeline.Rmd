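---
title: "Modelling annual wildfire probability with penalized-spline binomial GAMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling annual wildfire probability with penalized-spline binomial GAMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Annual wildfire probability over a large gridded landscape is shaped by three
interacting families of drivers: long-term climate (how much fuel a place can
grow and how dry it gets), human activity (ignitions near roads, power lines
and housing; suppression and fuel removal near agriculture and dense
development), and the recent fire history itself (a burn removes fuel and
temporarily suppresses re-burning). `pyrogam` implements a complete, testable
pipeline for estimating per-pixel annual fire probability from such layers at
a nominal 1-km resolution: covariate engineering, spatial thinning of
training data, a penalized-spline binomial generalized additive model (GAM),
spatiotemporal blocked cross-validation, and a counterfactual decomposition
of predictions into climate, human-activity and time-since-fire
contributions.

Because the real data products this kind of analysis consumes (gridded water
balance models, land cover, fire perimeter archives, census-derived housing
projections) are large external downloads, the package ships a first-class
synthetic-landscape generator with a *known* additive ground truth. Every
stage of the pipeline is validated against that truth, so the test suite
demonstrates that the machinery recovers what it should — a property that can
never be checked directly on real data, where the truth is unknown.

## The model

For pixel $i$ in year $t$, the burned indicator $y_{it} \in \{0, 1\}$ is
modelled as Bernoulli with

$$\mathrm{logit}\, p_{it} = \beta_0 + \sum_{j=1}^{9} s_j(x_{ijt}),$$

where the nine covariates are:

| covariate | units | meaning |
|---|---|---|
| `aet_normal` | mm | base-period mean annual actual evapotranspiration (fuel amount proxy) |
| `cwd_normal` | mm | base-period mean annual climatic water deficit (fuel dryness proxy) |
| `aet_dev3`, `cwd_dev3` | mm | mean deviation from the normal over the three years *preceding* the year of interest |
| `housing_density_25km` | units/ha | mean housing density within a 25-km radius |
| `cultivated_fraction` | proportion | cultivated fraction of the pixel |
| `dist_roads`, `dist_electrical` | km | Euclidean distance to the nearest road / electrical infrastructure cell |
| `years_since_fire` | years | years since the most recent recorded burn, capped at 100 |

Each $s_j$ is a cubic regression spline with a curvature penalty
$\lambda_j \int s_j''(x)^2\,dx$. The basis is parameterized by the spline's
values at $k$ knots with natural end conditions, which yields an *exact*
penalty matrix $S = D^\top B^{-1} D$ whose null space is the straight lines;
the construction works for any $k \ge 3$. Each smooth carries a sum-to-zero
constraint (absorbed by reparameterization, leaving $k - 1$ coefficients) so
it is identifiable alongside the intercept. Fitting maximizes the penalized
Bernoulli log-likelihood by penalized IRLS with step halving, so the
penalized deviance is non-increasing by construction; convergence is declared
when its relative change falls below $10^{-8}$ (200-iteration cap). The
effective degrees of freedom (EDF) of each term is the trace of its block of
the influence matrix $(X^\top W X + S_\lambda)^{-1} X^\top W X$.

## Tunable parameters and defaults

* **Basis dimension `basis_dim = 5`.** "At most five smoothing terms per
  parameter" is read as basis dimension $k = 5$ per smooth, i.e. four free
  coefficients per term after the centering constraint. This is the reading
  consistent with reference degrees of freedom of 4 per term in the kind of
  statewide fit the package emulates; the parameter is exposed everywhere for
  other choices.
* **Knot placement.** Knots sit at quantiles (type 7) of the *unique*
  training values of each covariate, which keeps them strictly increasing for
  heavily tied covariates such as `years_since_fire`; if quantiles still
  collide, an equally spaced fallback over the training range is used.
* **Smoothness selection.** By default a single $\lambda$ shared across terms
  is chosen by generalized cross-validation, $\mathrm{GCV}(\lambda) = n D /
  (n - \mathrm{EDF})^2$, over the log-spaced grid $10^{-3}, \dots, 10^{7}$
  (11 points, warm-started). A fixed scalar or per-term vector is accepted
  wherever speed matters more than automatic selection (the cross-validation
  helpers pass it through).
* **Out-of-range prediction clamps** each covariate to its training range
  rather than extrapolating the cubic — deliberately conservative, because
  the blocked cross-validation asks the model to predict in novel regions and
  years where covariates stray beyond the training span.
* **Poisson-disk thinning `min_dist_km = 5`.** Training pixels are selected
  by dart-throwing over the candidate lattice in a seeded random order,
  accepting a pixel iff no previously accepted pixel lies strictly within the
  minimum distance. The result is maximal with respect to its insertion
  order, and `min_dist_km = 0` keeps everything. Distances are between cell
  centers.
* **Years-since-fire cap 100.** Pixels with no recorded prior burn are
  treated as having gone 100 years without fire. The year immediately after a
  burn has `years_since_fire = 1`, and burns in the query year itself are
  ignored for that year's covariate so the label is never leaked into its own
  predictor.
* **Cross-validation `n_groups = 10`.** Years and pixels are independently
  partitioned into ten near-equal random groups. Iteration $i$ trains with
  temporal group $i$ *and* spatial group $i$ held out, and scores ROC/AUC
  separately on the novel-locations, novel-years and novel-both cells. The
  default pairing runs 10 iterations (group $i$ with group $i$); a full
  $10 \times 10$ grid of combinations is available via `pairing = "full"`.
  AUC is pooled over all pixel-years in a test cell, and iterations whose
  test cell contains a single class are recorded as missing and dropped from
  means with their counts reported.

## The synthetic generator

`generate_landscape()` emulates the statistical structure the analysis
assumes, not any particular geography:

* **Climate normals** are spatially autocorrelated Gaussian fields (white
  noise smoothed with a Gaussian kernel whose bandwidth is set by the
  correlation range; sample mean/sd matched exactly). Annual layers add an
  independent smooth anomaly field per year (`anomaly_sd`, default 60 mm).
* **Housing density** is a smooth low background plus a few Gaussian urban
  cores, snapshotted decadally with monotone growth; cultivated and water
  fractions are inverse-logit transforms of correlated fields; roads and
  electrical lines are scattered straight lines; regions tile the grid into
  rectangles.
* **The fire process** draws, for every pixel and simulation year, an
  independent Bernoulli with probability
  $\mathrm{logit}^{-1}(\beta_0^{\mathrm{true}} + \sum_j f_j(x_j))$ evaluated
  at the *current* years-since-fire state, then updates the state. A 100-year
  unrecorded burn-in initializes the state, mirroring the left-censoring of
  real fire-perimeter archives. Fire *spread* is deliberately not modelled —
  the method estimates probability of presence, not contagion — so burns are
  independent across pixels given the covariates.
* **Default effect shapes** follow the qualitative structure this kind of
  analysis reports: hump-shaped AET (fire peaks at intermediate
  productivity), rise-then-fall CWD (probability declines again under severe
  deficit), a years-since-fire ramp that rises rapidly over the first ~20
  years then saturates, a moderate-density housing hump, strongly negative
  cultivation, mild deviation and distance effects. The default intercept
  (−4.3 log-odds) was chosen once to give a marginal annual burn probability
  of roughly 1–2%, a realistic regional rate; it is configurable because the
  marginal rate of any particular real archive is a property of that archive.

What the generator does *not* emulate: spatially contiguous fire perimeters
(and hence event-size distributions), vegetation-type dynamics, temporally
autocorrelated climate anomalies, and measurement error in any layer.
Passing tests therefore demonstrate that the estimator recovers a known
additive truth under realistic spatial structure and class imbalance — not
that real fire data satisfy the additive model.

## Numerical choices

* The curvature penalty is exact (no quadrature error); the fitter
  symmetrizes it and falls back to a $10^{-10}$-scaled ridge only if a
  weighted Hessian is numerically singular.
* P-IRLS weights are floored at $10^{-10}$ and probabilities clamped to
  $[10^{-12}, 1 - 10^{-12}]$ inside the deviance.
* Perfect separation in *unpenalized* fits (deviance collapsing to zero or
  exploding coefficients) triggers a warning and a small-ridge refit.
* AUC uses the Mann–Whitney convention via midranks, so ties count one half;
  single-class inputs are an explicit error at the scoring level and a
  recorded-missing value at the cross-validation level.
* Event-size filtering uses *strict* inequalities (an event of exactly the
  threshold area is dropped), matching reporting thresholds phrased as
  "greater than".
* Focal means renormalize by the in-grid, unmasked portion of the disk, so
  edge pixels are unbiased; the FFT implementation agrees with brute-force
  enumeration to $10^{-9}$ in the tests.
* The 3-year deviation window is strictly $\{t-3, t-2, t-1\}$ — the year
  under prediction is excluded.

## Design choices in open territory

* **Null values for counterfactual elimination** follow the mean/zero/max
  ladder: training mean for climate normals (no meaningful null), zero for
  housing density, cultivation and climate deviations, training maximum for
  distances (zero distance is where their influence is strongest).
  `years_since_fire` has no principled null; the package removes it at the
  training mean and flags every report row where that rule fired.
* **Regional cross-validation** reuses the statewide temporal grouping (so
  folds are matched across regions and with the statewide model, making the
  paired t-test well defined) and re-draws spatial groups within each region.
  A region spanning the entire plan reuses it verbatim, so a one-region
  landscape reproduces the statewide analysis exactly.
* **Leave-one-year-out fitting** (`fit_annual_gams()`) is provided alongside
  the pooled fit: per-year models trained on all other years, for workflows
  that never let a year predict itself. The pooled fit is the default
  elsewhere because the two agree closely when the number of years is large.
* **Decomposition scope:** correlations can be computed over the sampled
  (Poisson-disk) pixels or over all valid pixels; the acceptance script uses
  all valid pixels because the observed-frequency side is much better
  estimated with the full map.

## Problem sizes used by the tests and acceptance script

The suite exercises the estimator at sizes chosen to make its statistical
claims testable in minutes on one core: shape recovery uses a 64×64 grid ×
40 years (≈150,000 pixel-years); cross-validation behavior is checked on
24–32-pixel-wide grids; the statewide-vs-regional direction is averaged over
20 seeds of a 24×24 four-region landscape; the acceptance script runs a
96×96 grid × 40 years with 5-km thinning (≈10,000 training records). The
small-grid studies raise the generating intercept to ≈logit(0.04) so that
every held-out fold retains, in expectation, a handful of positive cases —
at a 1.5% rate and a few thousand records, many folds would otherwise be
single-class by chance, which is a property of the fold size, not of the
estimator.

## Known limitations

* At desk scale the observed mean annual frequency over ~40 years of a
  1–2% process is mostly zeros, so correlations against observed frequency
  have a low irreducible ceiling (≈0.27 in the acceptance configuration —
  the generating probability map itself correlates no better). Submodel
  rankings remain meaningful; absolute values do not transfer to long
  records.
* `years_since_fire` is endogenous: pixels that happen to burn are suppressed
  afterwards by the fitted ramp while the observed-frequency map counts those
  burns, and the recorded covariate is left-censored at the record start
  (never-burned-in-record pixels sit at the cap regardless of their true
  state). Both effects depress the full-model/observed correlation in short
  synthetic records relative to smooth exogenous submodels.
* The GCV grid search shares one $\lambda$ across terms; per-term optimization
  (and REML) are natural extensions but are not needed to meet any property
  the package asserts.
* Term-level chi-squared statistics in `summary()` are Wald approximations
  conditioning on the selected smoothing parameter, and are labelled as such.
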