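---
title: "Bayesian comparison of yield-monitor data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian comparison of yield-monitor data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yieldbayes)
```

## The problem

Combine harvesters with yield monitors record one dry-yield measurement
per harvested polygon — a cell whose area is the header (swath) width
times the distance travelled during one logging interval. Over a season
this produces hundreds to thousands of georeferenced measurements per
field. When some fields received a treatment (here: a winter field-pea
green manure incorporated before the cash crop) and neighbouring fields
did not, those polygons form a large, if messy, on-farm experiment: each
polygon is an observational unit, and the question is how much the
treatment shifted the yield distribution.

`yieldbayes` implements that analysis end to end:

1. **Data** — simulated or ingested polygon-level measurements
   (`field_id, group, x, y, area_m2, dry_yield_kg_ha` as CSV, or the
   same attributes on GeoJSON Point features).
2. **Filtering** — the 3-sigma rule: within each scope, measurements
   outside `mean ± 3·sd` are discarded (99.7% retention under
   normality).
3. **Balancing** — stratified random sampling with each field as a
   stratum, so both groups contribute the same number of measurements
   and no large field dominates.
4. **Estimation** — for each group, the posterior of the mean µ and
   standard deviation σ of a normal yield model, sampled by
   random-walk Metropolis MCMC.
5. **Contrast** — the posterior distribution of the test−control
   difference, its highest density interval (HDI), and the posterior
   probability that a test measurement exceeds a control one.

## The model

Within a group, dry yields are modelled as independent draws from
$y_i \sim \mathcal{N}(\mu, \sigma)$. By Bayes' theorem the posterior is
proportional to likelihood times prior; the evidence term is never
needed because MCMC works with the unnormalised density. Priors are
weakly informative and data-scaled:

$$\mu \sim \mathcal{N}(\bar y,\; 10\, s_y), \qquad
  \sigma \sim \text{HalfNormal}(10\, s_y),$$

with $\bar y$ and $s_y$ the sample mean and sd. The factor 10
(`prior_scale_factor`, configurable and recorded in every fit) makes
the priors broad on the data's own scale while keeping the posterior
proper; at the sample sizes involved (hundreds per group) the
likelihood dominates and the exact factor is immaterial.

The iid-normal likelihood is a deliberate simplification: yield
monitor data are spatially correlated and mildly skewed. The design
compensates at the data level (neighbouring-field pairing, polygon-level
comparison, 3-sigma filtering) rather than in the likelihood; a
hierarchical or spatially correlated model is out of scope.

### Sampler

The sampler is random-walk Metropolis over $(\mu, \log\sigma)$, with the
Jacobian correction so the chain targets the posterior of
$(\mu, \sigma)$. Sampling $\sigma$ on the log scale removes the
positivity boundary and improves mixing without changing the posterior.
Proposals are diagonal Gaussian; initial scales are set to roughly the
posterior scale ($2.4\,s_y/\sqrt n$ for µ, $2.4/\sqrt{2n}$ for
log σ) and, during burn-in only, multiplicatively adapted every 50
iterations towards an acceptance rate of about 0.3. Adaptation stops at
the end of burn-in, so the retained transitions leave the posterior
invariant. Defaults: 4 chains, 5000 iterations, 1000 burn-in.

Likelihood evaluations inside the chain use the sufficient statistics
$(n, \bar y, \sum_i (y_i - \bar y)^2)$, which is algebraically identical
to the per-point sum (a unit test asserts the equality) and makes each
iteration O(1) in the data size.

Convergence is checked with the split-chain potential scale reduction
statistic (R-hat) and an autocorrelation-based effective sample size
(Geyer initial monotone sequence). `fit_group()` refuses to return a
posterior whose R-hat exceeds 1.01 — an error carrying the diagnostics,
never a silent bad fit. Correctness of the sampler is established two
independent ways in the test suite: dense grid integration of the
unnormalised posterior over $(\mu, \sigma)$, and the conjugate
normal–normal closed form when σ is held fixed.

### Contrast distribution

Two contrast modes are provided because they answer different
questions and the difference matters in practice:

* **parameter** — draw $i$ is $\mu_T[i] - \mu_C[i]$: the posterior of
  the difference in *group means*. Its mean equals the difference of
  the posterior means.
* **predictive** (default) — one simulated measurement
  $\tilde y_g[i] \sim \mathcal{N}(\mu_g[i], \sigma_g[i])$ is drawn per
  posterior draw for each group and differenced: the distribution of
  the difference between matched simulated measurement pairs. Its mean
  has the same centre but the spread includes within-group variability,
  so statements made from it concern measurements, not just means.

Published analyses of this kind report the contrast as the mean of
matched-pair differences rather than the difference of group means,
which is why the predictive mode is the default; the mode is recorded
in every result.

From the contrast draws the package reports:

* the **contrast mean** (kg/ha);
* the **95% HDI** — the shortest contiguous interval containing 95% of
  the sorted draws (the unimodal estimator; mass configurable). The
  implementation is an O(n log n) sorted window scan, tested against
  an exhaustive brute-force search;
* the **probability of superiority** — the fraction of contrast draws
  above zero, with draws exactly at zero counted half (unbiased under
  continuous distributions, deterministic). Under the predictive mode
  this is the posterior probability that a treated measurement exceeds
  a control one, which is how "the percentage of the observed area
  where the effect is statistically evident" is operationalised;
* the **gain**, `100 · (µ_T − µ_C)/µ_C`, rounded half-up to an integer
  percent. Displayed yields are rounded to the nearest 10 kg/ha; full
  precision is kept in the machine-readable output.

## The synthetic-data generator

No public accession of the original yield-monitor records exists, so
the generator is a first-class module that reproduces the *structure*
the analysis relies on:

* **Geometry** — rectangular fields tiled into polygons of
  swath × (speed × interval); edge polygons are truncated rather than
  discarded so each field's polygon areas sum exactly to its area (a
  tested invariant). Defaults (7.2 m, 2 m/s, 3 s → 43.2 m² polygons)
  describe a typical mid-size combine; no machine constants were
  published, so these are free parameters.
* **Fertility surface** — smooth spatial variation is a seeded lattice
  of iid standard normals combined with a Gaussian kernel of bandwidth
  `fertility_scale` and standardised pointwise, so the marginal sd is
  exactly `fertility_sd` everywhere and correlation decays on the
  configured length scale. Any smooth, seeded, correlation-length-
  controlled surface would satisfy the contract; this one makes the
  marginal-sd invariant exactly testable. One surface spans *all*
  fields of a run, so neighbouring test and control fields share local
  trends — the design feature that motivates neighbouring-field
  comparison.
* **Yield model** — group mean (2550 kg/ha control baseline, +990
  kg/ha treatment effect by default, matching the scale of the wheat
  study the package emulates), plus the surface, plus independent
  `N(0, noise_sd²)` noise; with probability `outlier_rate` the noise is
  replaced by ±`outlier_magnitude · noise_sd` to emulate monitor
  glitches. Yields are clipped at zero (yield is physical); clipping is
  counted and logged. Defaults `fertility_sd = 350`, `noise_sd = 450`
  kg/ha and `outlier_rate = 0.002` give within-field coefficients of
  variation around 15–20%, typical of cereal yield maps.
* **Seeding** — one master seed drives independent substreams
  (surface, noise, outliers, sampling, chains, predictive draws), so
  any stage can be regenerated alone and a full run is bit-reproducible.

What the generator does **not** emulate: harvester kinematics beyond
straight passes, moisture correction, GPS artefacts (overlap passes,
fill delays), or real field boundaries. Passing tests on synthetic data
therefore demonstrate that the *inference machinery* is correct under
its assumptions, not that the model is adequate for any particular real
dataset.

## Numerical and design choices

* **Filter scope** — mean and sd are computed per group (test and
  control separately, `scope = "group"`), so a genuine treatment effect
  cannot push valid measurements of the other group outside the bounds.
  Filtering is single-pass: bounds from the unfiltered data, applied
  once. A zero-sd scope keeps everything (bounds collapse); a scope
  with fewer than two measurements is an error naming the scope.
* **Allocation rounding** — proportional stratum allocations use
  largest-remainder rounding with ties broken by lexicographic
  `field_id`, making the sampling plan deterministic given the seed.
  The default target per group is the smaller group's size.
* **HDI ties** — when several windows share the minimal width the
  lowest window is taken; deterministic, and immaterial for continuous
  draws.
* **Degenerate inputs** — σ ≤ 0 yields a log posterior of −∞
  (rejected proposal) rather than an exception; zero-variance chains
  give R-hat 1 with a warning; degenerate field geometry (smaller than
  one polygon) is an explicit error.
* **Calibration checks** — the replicated coverage test simulates from
  the iid model (fertility surface off) so that it isolates the
  sampler's frequentist calibration; with a strong spatially correlated
  surface the effective sample size of a field is smaller than the
  polygon count and nominal coverage of group-mean intervals degrades.
  That is a property of the iid likelihood on spatial data — documented
  here as a limitation — not of the sampler. Test problem sizes
  (n = 500–1000 per group, 20 replicates, 10⁶ draws for the
  filter/HDI asymptotics) were chosen to keep Monte-Carlo error well
  inside the asserted tolerances.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  location = "DEMO",
  layouts  = example_layouts(n_pairs = 3, width = 100, length = 400),
  sim      = sim_config(baseline_mean = 2550, treatment_effect = 990),
  target_per_group = 1000,
  seed     = 1
)
rep <- run_pipeline(cfg)
report_table(rep)
plot(rep)   # group posteriors | contrast + HDI | P(superiority)
```

The report's provenance block (config, derived stage seeds, filter
report, sampling plan) is sufficient to reproduce the run exactly;
re-running with the same config yields identical measurements, chains
and report.

## Known limitations

* The normal likelihood ignores spatial correlation and skew; effects
  on interval calibration are discussed above.
* The polygon-level pairing cancels shared local trends only insofar as
  test and control fields are genuinely neighbours; the generator's
  paired layout makes this explicit, real layouts may not.
* The probability of superiority is a posterior statement under the
  model, not a design-based area estimate; interpreting it as "% of
  observed area" inherits the model's assumptions.
* No moisture correction, GPS cleaning, or hierarchical field-level
  modelling; the only filter is the 3-sigma rule.
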