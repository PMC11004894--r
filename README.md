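# yieldbayes

Bayesian comparison of combine yield-monitor data between treated
(green-manure) and control fields.

Modern harvesters log one dry-yield measurement per harvested polygon —
a cell of swath width × (speed × logging interval), tens of m² — which
turns a handful of commercial fields into an experiment with hundreds
to thousands of observational units per group. `yieldbayes` is the
analysis pipeline for that setting, aimed at agronomists and
precision-agriculture analysts:

1. **simulate / ingest** polygon-level measurements
   (CSV `field_id,group,x,y,area_m2,dry_yield_kg_ha`, or GeoJSON
   points with the same properties);
2. **filter** gross outliers with the 3-sigma rule (per group:
   keep `mean ± 3·sd`, 99.7% retention under normality);
3. **balance** the groups by stratified random sampling — each field a
   stratum, proportional allocation, equal totals per group;
4. **fit** each group's yield distribution `y ~ N(mu, sigma)` by
   random-walk Metropolis MCMC with data-scaled weakly informative
   priors (`mu ~ N(ybar, 10·s)`, `sigma ~ HalfNormal(10·s)`),
   split-chain R-hat and effective-sample-size diagnostics;
5. **contrast** the groups: the posterior distribution of the
   test−control difference (parameter mode `mu_T − mu_C`, or the
   default predictive mode differencing matched simulated measurement
   pairs), its 95% highest density interval, the probability of
   superiority `P(y_T > y_C | data)`, and the relative gain
   `100·(mu_T − mu_C)/mu_C` (%).

The MCMC sampler, R-hat/ESS diagnostics, HDI estimator and contrast
machinery are implemented in the package and verified in the test suite
against independent oracles (dense grid integration of the posterior,
conjugate closed forms, brute-force HDI search).

## Worked example

```r
library(yieldbayes)

cfg <- pipeline_config(
  location = "DEMO",
  layouts  = example_layouts(n_pairs = 3, width = 100, length = 400),
  sim      = sim_config(baseline_mean = 2550, treatment_effect = 990),
  target_per_group = 1000,
  seed     = 1
)
rep <- run_pipeline(cfg, verbose = FALSE)
rep
```

```
Analysis report — DEMO
  mu_test         3590 kg/ha
  mu_control      2540 kg/ha
  contrast        1060 kg/ha  (predictive mode)
  gain              41 %
  95% HDI     [-580, 2680] kg/ha
  superiority       90 % of observed area
```

Read: the simulation planted a true +990 kg/ha effect on a 2550 kg/ha
baseline; the posterior group means recover those (up to the shared
fertility surface's field-to-field variation), the predictive contrast
mean estimates the per-polygon treatment difference, its wide HDI
reflects within-field measurement spread (not uncertainty about the
mean difference — use `contrast_mode = "parameter"` for that), and
the treated yield exceeds the control on about 90% of matched draws.
`plot(rep)` draws the three-panel figure (group posteriors, contrast
with HDI, superiority).

A shell interface wrapping the same functions lives at
`inst/cli/yieldbayes.R` (subcommands `simulate`, `filter`, `sample`,
`fit`, `contrast`, `report`, `run`).

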