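# agbgeo

Bayesian geostatistical estimation of forest aboveground biomass (AGB) from
field plots and airborne-lidar canopy structure metrics.

Sparse plot networks cannot map subalpine forest carbon on their own, and
optical satellite products saturate at high biomass. `agbgeo` implements the
middle path: plot-level AGB densities are regressed on gridded lidar metrics
inside a spatial hierarchical model, which predicts AGB at 30 m pixels with
honest uncertainty and integrates the pixels into management-unit totals
with credible intervals.

## The model

For square-root transformed AGB density `y(s)` (Mg/ha) at plot location `s`:

```
y(s) = beta0 + beta1 x1(s) + beta2 x2(s) + beta3 x3(s) + w(s) + eps(s)
```

with `w(s)` a zero-mean Gaussian process with exponential covariance
`sigma2 * exp(-phi * d)` (partial sill `sigma2`, decay `phi`, effective
range `-ln(0.05)/phi`) and `eps(s) ~ N(0, tau2)` an iid nugget. A null model
(intercept + `w` only) quantifies the inherent spatial dependence of AGB via
the nugget-to-sill ratio `tau2 / (tau2 + sigma2)`. Models are fit by MCMC on
the marginalized likelihood `y ~ N(X beta, sigma2 R(phi) + tau2 I)`;
pixel-level posterior predictive distributions come from composition
sampling and are squared back to the AGB scale. The pipeline covers:

* `aggregate_plot_agb()` — tree records to plot AGB density (inclusive
  7.6 cm DBH threshold, live + dead, cluster expansion);
* `compute_metric_grid()` / `extract_plot_metrics()` — the 17 candidate
  canopy metrics (cover, mean/SD height, 13 percentiles, rumple) on a 30 m
  grid, with the 64 m / 40 m height-artifact mask;
* `select_best()` — exhaustive 2- and 3-metric OLS screening of
  `sqrt(AGB)` (816 candidate subsets), ranked by adjusted R²;
* `run_mcmc()`, `composition_predict()`, `predict_agb()` — Bayesian fit
  and pixel prediction (Est, SD, RSD, 95% CI per pixel);
* `mu_joint_estimate()` — per-draw integration to management-unit totals;
* `cv_run()` — ten-fold cross-validation with empirical 95% coverage;
* `generate_plot_dataset()` and friends — a seeded synthetic-data module
  reproducing the spatial-dependence and metric-correlation structure the
  analysis assumes, so everything is testable end to end;
* `run_pipeline()` — seeded orchestration with per-stage manifests.

## Worked example

```r
library(agbgeo)

# synthetic study: 360 clustered plots, 17 candidate metrics
d <- generate_plot_dataset(sim_config(seed = 42))

# screen all 816 two-/three-metric OLS models of sqrt(AGB)
sel <- select_best(d$plots$agb_sqrt, d$metrics)
print(sel, n = 2)
#> Exhaustive 2-/3-metric OLS screening: 816 candidates
#> best subset: canopy_cover_pct + mean_height_m + rumple
#>                                  subset size     r2 adj_r2  aic rank
#> 1 canopy_cover_pct,mean_height_m,rumple    3 0.8175 0.8160 1568    1
#> 2              mean_height_m,p30,rumple    3 0.8072 0.8056 1587    2

# Bayesian geostatistical fit on the selected metrics
fit <- run_mcmc(d$plots, d$metrics, model_spec("covariate", sel$best),
                config = mcmc_config(n_iter = 4000, n_burn = 1000, thin = 3,
                                     seed = 7))
print(fit)
#> Bayesian geostatistical fit (covariate model), n = 360 plots
#> retained draws: 1000; Metropolis acceptance: 0.27
#>          parameter     q50    q2.5   q97.5
#> 1      (Intercept) -1.1552 -1.7689 -0.4960
#> 2 canopy_cover_pct  0.0456  0.0297  0.0606
#> 3    mean_height_m  0.3686  0.2850  0.4484
#> 4           rumple  2.1808  1.6970  2.6491
#> 5           sigma2  3.5274  2.4576  4.4430
#> 6             tau2  0.8354  0.3435  1.8718
#> 7              phi 11.9942  7.6520 20.1909
#> 8     eff_range_km  0.2498  0.1484  0.3915
```

The posterior medians sit close to the generative truth (`beta = (-1.45,
0.05, 0.42, 2.0)`, `sigma2 = 4.2`, `tau2 = 0.72`, effective range 0.30 km),
and the selected trio is exactly the planted signal. The partial sill
dominates the nugget: `nugget_to_sill(0.84, 3.53)` ≈ 0.19 for the covariate
model's residual structure, and lower still for a null-model fit on the
same data, whose `sigma2` also absorbs the spatially structured metric
signal.

Downstream, `predict_agb(fit, grid)` returns per-pixel `est`, `sd`,
`rsd_pct`, `ci_lo`, `ci_hi`; `mu_joint_estimate()` turns pixel draws into
management-unit totals in Tg with credible intervals; `cv_run()` reports
RMSE, RSE, R², bias, 95% coverage and mean interval width.

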