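---
title: "Bayesian geostatistical estimation of forest aboveground biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian geostatistical estimation of forest aboveground biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agbgeo)
```

## The problem

Subalpine forests hold substantial carbon, but their aboveground biomass
(AGB) is hard to map: field plots are sparse, stand structure is patchy, and
optical satellite products saturate at high biomass and over-predict in open
rocky terrain. `agbgeo` implements a plot + airborne-lidar workflow for this
setting: plot-level AGB densities are regressed on gridded canopy-structure
metrics inside a Bayesian geostatistical model, which is then used to predict
AGB at 30 m pixels and to integrate those predictions into management-unit
(MU) totals with full posterior uncertainty.

## The model

Let $y(s)$ be square-root transformed AGB density (Mg/ha) at plot location
$s$. The covariate model is

$$ y(s) = \beta_0 + \beta_1 x_1(s) + \beta_2 x_2(s) + \beta_3 x_3(s) + w(s) + \varepsilon(s), $$

where $x_1,x_2,x_3$ are the three selected lidar metrics, $w(s)$ is a
zero-mean Gaussian process with exponential covariance
$\mathrm{Cov}(w(s),w(s')) = \sigma^2 e^{-\phi\,\|s-s'\|}$, and
$\varepsilon(s) \sim N(0,\tau^2)$ is iid micro-scale/measurement error. The
null model keeps only $\beta_0$ and is used to quantify the inherent spatial
dependence of AGB: its nugget-to-sill ratio $\tau^2/(\tau^2+\sigma^2)$ is
small when AGB is strongly spatially structured. Because the exponential
covariance approaches zero only asymptotically, spatial reach is reported as
the *effective range* $-\ln(0.05)/\phi$, the distance at which correlation
drops to 0.05.

The square-root transform stabilizes the variance of plot AGB (which is
strongly right-skewed); predictions are made on the square-root scale and
squared afterwards. Negative square-root-scale predictive draws are squared
as-is — the back-transform maps the whole predictive distribution onto the
non-negative AGB scale, and truncating before squaring would bias the
low-biomass tail.

### Why each piece is there

* **Metric screening** (`select_best()`): all $\binom{17}{2}+\binom{17}{3}=816$
  two- and three-metric OLS models of $\sqrt{AGB}$ are fit and ranked by
  adjusted $R^2$, ties broken by AIC, then smaller subset, then name order.
  Collinearity among the winners is tolerated on purpose: the goal is
  prediction, not attribution, and canopy cover, mean height and rumple are
  intrinsically correlated descriptions of the same canopy.
* **Marginalized MCMC** (`run_mcmc()`): $w$ is integrated out analytically,
  so the sampler works on $y \sim N(X\beta,\ \sigma^2 R(\phi) + \tau^2 I)$
  with a conjugate Gibbs update for $\beta$ and an adaptive random-walk
  Metropolis update for $(\log\sigma^2, \log\tau^2, \mathrm{logit}\,\phi)$.
  Sampling $w$ jointly with the parameters would add $n$ highly correlated
  dimensions and mix far worse; the marginal and hierarchical forms have the
  same joint posterior (verified by quadrature in the tests). Spatial effects
  are recovered afterwards, one draw of $w \mid y, \beta, \theta$ per
  retained sample.
* **Composition sampling** (`composition_predict()`): for each retained
  draw, the spatial effect at a new site is drawn from its Gaussian-process
  conditional given that draw's $w$ at the plots, then the nugget is added.
  Parameter uncertainty therefore propagates into every pixel's posterior
  predictive distribution (PPD).
* **Per-draw areal integration** (`mu_joint_estimate()`): MU totals are
  computed per draw (average the MU's pixels, multiply by area) and
  summarized afterwards. Summing pixel medians would discard the spatial
  covariance of prediction errors and understate interval widths. The
  relative SD of an MU's total and of its mean density are identical by
  construction, since both are the same draws scaled by area.

## Priors and numerical choices

"Vague" priors are made concrete as: $\beta \sim N(0, 10^4)$ per
coefficient; $\sigma^2, \tau^2 \sim$ inverse-gamma with shape 2 and scale
half the OLS residual variance of $y$ on the model's design (for the null
model, half $\mathrm{var}(y)$). Centering the variance priors on the scale
the model actually has to partition keeps them diffuse where the posterior
lives; scaling them to the raw response variance instead makes them sharply
informative *against* small residual variances once covariates explain most
of the signal (an inverse-gamma with scale near $\mathrm{var}(y)/2$ puts
vanishing density on a nugget an order of magnitude smaller), which is
exactly the covariate-model regime. The parameter-recovery test exercises
interval calibration under the shipped prior. $\phi$ is uniform over decays whose effective range spans the
observed pairwise-distance range (minimum distance floored at one 30 m cell).

Other conventions, pinned so independent oracles can match results exactly:

* Height percentiles use linear interpolation between order statistics
  (R's type-7 default); the canopy threshold is strictly "> 2 m".
* The rumple CHM is built at 1 m resolution from the highest return per fine
  cell (empty fine cells count as ground) and triangulated with a fixed
  NW–SE diagonal, so the surface area is deterministic.
* Exact duplicate plot locations are jittered by 1 m with a warning (they
  make the marginal covariance singular as $\tau^2 \to 0$); a failed
  Cholesky factorization is retried once with $10^{-8}\sigma^2$ added to the
  diagonal, also with a warning.
* Proposal scales adapt only during burn-in (batches of 50, targeting ~30%
  acceptance), so the retained chain is a fixed-kernel Markov chain.
* Pixel PPD medians and quantiles are computed on the squared draws
  directly; the square of the median is not the median of the squares once
  negative square-root-scale draws exist.
* New-site spatial draws are conditionally independent across pixels given
  each retained $w$ draw. This is exact for every single-pixel summary and
  for calibration against per-pixel truth; it slightly understates
  cross-pixel dependence in areal aggregation, so an exact joint-conditional
  mode (`mode = "joint"`, up to 2000 pixels) is available and agrees with
  the independent mode marginally (tested); the joint mode is preferred for
  areal work when the pixel count allows it.

## What the synthetic generator emulates — and what it does not

`generate_plot_dataset()` reproduces the statistical structure the analysis
assumes, with defaults chosen once to mirror the study conditions:

* 360 plots over a 10 × 10 km domain, *clustered* (parent sites with 150 m
  normal offsets, reflected at the domain edge) the way inventory and
  monitoring designs cluster plots around visited locations. Clustering
  matters: it produces the short pairwise distances that identify $\phi$
  and the nugget.
* Square-root-scale variance components $\sigma^2 = 4.2$, $\tau^2 = 0.72$,
  effective range 0.3 km — strong spatial dependence with a small
  nugget-to-sill ratio, matching the posterior scale of the fitted models.
* Three signal metrics (canopy cover %, mean height m, rumple) that share
  one landscape-scale latent structure field (effective range 2 km) plus
  metric-specific noise. The loadings are solved numerically so the
  metric–$\sqrt{AGB}$ correlations hit 0.74 / 0.84 / 0.85; a shared latent
  is *necessary*, since $0.74^2+0.84^2+0.85^2 \approx 1.98 > 1$ rules out
  mutually independent metrics. The implied inter-metric correlations
  (≈0.67/0.74/0.85) and the best-model adjusted $R^2$ (≈0.8) then emerge
  rather than being imposed.
* 14 decoy metrics (height SD and 13 percentiles) built as noisy mixtures of
  the signal metrics, so exhaustive selection faces realistic confusable
  candidates.
* The response is built exactly as $y = \beta_0 + \beta^\top x + w +
  \varepsilon$, so refitting the model on generated data is a genuine
  parameter-recovery experiment.

What it does **not** emulate: species composition, fire effects (the main
real-world source of cover–AGB decoupling), terrain, lidar acquisition
artifacts beyond the height-threshold mask, and non-Gaussian residual
structure. Passing calibration tests on this generator shows the
*machinery* is correct and internally calibrated; it does not certify
accuracy on real plots.

The per-plot tree lists (`generate_tree_list()`) use a placeholder power-law
allometry $a\,\mathrm{DBH}^b$ — a stand-in that exercises the aggregation
rules (inclusive 7.6 cm DBH threshold, live + dead, cluster expansion,
kg→Mg/area conversion), not a calibrated biomass equation. Real per-tree AGB
is an upstream input.

## Problem sizes and chain lengths used in the shipped checks

Full-analysis defaults are 25,000 iterations (5,000 burn-in, thin 10). The
package's own tests and the acceptance script use deliberately smaller but
statistically adequate sizes, chosen as a design point: 4,000-iteration
chains (1,000 burn-in, thin 3) for single fits and parameter recovery at
$n = 300$–360, 3,000-iteration chains per fold for the ten-fold
cross-validation, a 30 × 30 pixel grid for predictive calibration, and 20
seeded replicates for recovery/selection frequency checks. At these sizes
the Monte-Carlo error of a 95% interval endpoint is small relative to the
intervals themselves, and the calibration bands used in the tests
(coverage within 92–98%) absorb the residual simulation noise.

## Known limitations and conflicts noted

* Reported source values contain two internal inconsistencies we surfaced
  while validating arithmetic: a null-model partial sill printed as 22.48
  in the parameter table but 20.48 in the text (the table value reproduces
  the printed nugget-to-sill of 0.04), and cross-validated RMSE/RSE printed
  as 49.06/27.41% in the table but 49.2/27.56% in the text. The package
  always reports what it computes.
* "RSE" is implemented as relative *squared* error
  ($100\sum(\hat y - y)^2 / \sum(y-\bar y)^2$): only this definition is
  consistent with a near-zero-skill null model scoring ≈106% alongside
  $R^2 = 0.01$, and $R^2$ is the squared Pearson correlation for the same
  reason.
* The exhaustive search stops at three metrics by design; no regularized or
  cross-validated selection is attempted.
* Dense covariance algebra limits fits to a few thousand plots; no
  low-rank/nearest-neighbor GP approximations are included.
* Grids are plain data frames read/written as CSV; georeferenced raster
  I/O is out of scope.
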