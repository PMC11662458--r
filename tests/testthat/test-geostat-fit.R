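test_that("exponential covariance honors its limits and stays positive semi-definite", {
  expect_equal(exp_covariance(0, 3.5, 2), 3.5)
  expect_equal(exp_covariance(-log(0.05) / 2, 3.5, 2), 0.05 * 3.5)
  set.seed(2)
  D <- as.matrix(dist(matrix(runif(10), 5, 2)))
  S <- exp_covariance(D, 2, 4)
  expect_true(isSymmetric(S))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(exp_covariance(matrix(-1, 1, 1), 1, 1), "negative")
})

test_that("effective range is -log(0.05)/phi and strictly decreasing", {
  expect_equal(effective_range(-log(0.05)), 1)
  expect_equal(effective_range(-log(0.05) * 10), 0.1)
  phis <- c(0.5, 1, 5, 20, 100)
  expect_true(all(diff(effective_range(phis)) < 0))
  expect_error(effective_range(0), "> 0")
})

test_that("marginalized likelihood matches the standard-normal case and a dense oracle", {
  d1 <- matrix(0, 1, 1)
  expect_equal(log_marginal_likelihood(0, NULL, NULL, 0.4, 0.6, 1, d1),
               -0.5 * log(2 * pi))

  set.seed(7)
  xy <- matrix(runif(6), 3, 2)
  D <- as.matrix(dist(xy))
  y <- c(1.3, -0.2, 0.8)
  X <- cbind(1, c(0.5, 1.1, -0.3))
  beta <- c(0.4, 0.9)
  S <- 1.7 * exp(-2.5 * D) + 0.6 * diag(3)
  expect_equal(log_marginal_likelihood(y, X, beta, 1.7, 0.6, 2.5, D),
               naive_mvn_logdens(y, drop(X %*% beta), S), tolerance = 1e-10,
               ignore_attr = TRUE)

  # translation invariance: shifting y and the mean together changes nothing
  expect_equal(log_marginal_likelihood(y + 3, X, c(beta[1] + 3, beta[2]),
                                       1.7, 0.6, 2.5, D),
               log_marginal_likelihood(y, X, beta, 1.7, 0.6, 2.5, D))
})

test_that("marginalized likelihood equals the hierarchical model integrated over w", {
  # 2-plot toy: integrate N(y | X beta + w, tau2 I) N(w | 0, sigma2 R) dw by
  # quadrature and compare with the marginalized Gaussian
  y <- c(1.2, 0.7); beta <- 0.5; sigma2 <- 0.8; tau2 <- 0.5; phi <- 2
  D <- matrix(c(0, 0.3, 0.3, 0), 2)
  R <- exp(-phi * D)
  gr <- seq(-6 * sqrt(sigma2), 6 * sqrt(sigma2), length.out = 601)
  h <- diff(gr[1:2])
  Rinv <- solve(sigma2 * R)
  dens <- outer(gr, gr, function(w1, w2) {
    lw <- -0.5 * (Rinv[1, 1] * w1^2 + 2 * Rinv[1, 2] * w1 * w2 + Rinv[2, 2] * w2^2) -
      log(2 * pi) - 0.5 * determinant(sigma2 * R)$modulus
    ly <- dnorm(y[1], beta + w1, sqrt(tau2), log = TRUE) +
      dnorm(y[2], beta + w2, sqrt(tau2), log = TRUE)
    exp(lw + ly)
  })
  quad <- log(sum(dens) * h^2)
  marg <- log_marginal_likelihood(y, matrix(1, 2), beta, sigma2, tau2, phi, D)
  expect_equal(marg, quad, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("beta draws under fixed covariance parameters match closed-form GLS", {
  set.seed(10)
  n <- 25
  coords <- matrix(runif(2 * n, 0, 2), n, 2)
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n, 0, 0.8)
  plots <- data.frame(x_km = coords[, 1], y_km = coords[, 2], agb_sqrt = y)
  mets <- data.frame(x = x)
  # freeze the covariance parameters at their initial values with a
  # vanishing proposal scale; the beta Gibbs draws are then iid from the
  # exact Gaussian conditional
  cfg <- mcmc_config(n_iter = 3200, n_burn = 200, thin = 1,
                     proposal_scale = c(log_sigma2 = 1e-12, log_tau2 = 1e-12,
                                        phi = 1e-12),
                     adapt = FALSE, seed = 3)
  fit <- suppressWarnings(
    run_mcmc(plots, mets, model_spec("covariate", "x"), config = cfg,
             recover_w = FALSE))
  # reconstruct the frozen covariance (the sampler's documented inits)
  X <- cbind(1, x)
  v0 <- var(qr.resid(qr(X), y))
  pr <- default_priors(y, coords, X)
  S <- (v0 / 2) * exp(-sqrt(pr$phi_lower * pr$phi_upper) *
                        as.matrix(dist(coords))) + (v0 / 2) * diag(n)
  Vb <- solve(t(X) %*% solve(S, X) + diag(1e-4, 2))
  mb <- Vb %*% t(X) %*% solve(S, y)
  bd <- fit$samples$beta
  expect_equal(unname(colMeans(bd)), drop(mb),
               tolerance = 6 / sqrt(nrow(bd)), ignore_attr = TRUE)
  expect_equal(unname(apply(bd, 2, sd)), sqrt(diag(Vb)), tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("nugget-to-sill covers the pure-spatial and pure-nugget limits", {
  expect_equal(round(nugget_to_sill(0.83, 22.48), 2), 0.04)
  expect_equal(nugget_to_sill(0, 5), 0)
  expect_equal(nugget_to_sill(5, 0), 1)
  expect_error(nugget_to_sill(0, 0), "both")
})

test_that("posterior summaries reduce to their quantile definitions", {
  const <- list(beta = matrix(2.5, 500, 1, dimnames = list(NULL, "b0")),
                sigma2 = rep(1, 500), tau2 = rep(0.3, 500),
                phi = rep(4, 500), eff_range_km = rep(effective_range(4), 500))
  s <- summarize_posterior(const)
  expect_equal(unlist(s[1, c("q50", "q2.5", "q97.5")]), c(2.5, 2.5, 2.5),
               ignore_attr = TRUE)

  set.seed(1)
  z <- rnorm(10000)
  norm <- list(beta = matrix(z, ncol = 1, dimnames = list(NULL, "b0")),
               sigma2 = abs(z) + 1, tau2 = abs(z) + 1, phi = abs(z) + 1,
               eff_range_km = effective_range(abs(z) + 1))
  sn <- summarize_posterior(norm)
  expect_equal(unlist(sn[1, c("q50", "q2.5", "q97.5")]), c(0, -1.96, 1.96),
               tolerance = 0.05, ignore_attr = TRUE)
  # effective range is a monotone decreasing transform of phi, so its
  # quantiles are the transformed, order-reversed phi quantiles
  expect_equal(sn$q50[sn$parameter == "eff_range_km"],
               effective_range(sn$q50[sn$parameter == "phi"]))
  expect_equal(sn$q2.5[sn$parameter == "eff_range_km"],
               effective_range(sn$q97.5[sn$parameter == "phi"]))
})

test_that("the sampler is seed-reproducible and handles degenerate inputs", {
  d <- tiny_dataset(40)
  cfg <- mcmc_config(n_iter = 700, n_burn = 200, thin = 2, seed = 5)
  spec <- model_spec("covariate", signal_metrics)
  f1 <- run_mcmc(d$plots, d$metrics, spec, config = cfg, recover_w = TRUE)
  f2 <- run_mcmc(d$plots, d$metrics, spec, config = cfg, recover_w = TRUE)
  expect_identical(f1$samples, f2$samples)
  expect_true(all(f1$samples$sigma2 > 0) && all(f1$samples$tau2 > 0))
  expect_true(all(f1$samples$phi >= f1$priors$phi_lower &
                    f1$samples$phi <= f1$priors$phi_upper))
  expect_equal(length(f1$samples$sigma2), (700 - 200) / 2)

  dup <- d$plots; dup$x_km[2] <- dup$x_km[1]; dup$y_km[2] <- dup$y_km[1]
  expect_warning(run_mcmc(dup, d$metrics, spec, config = cfg,
                          recover_w = FALSE), "jittered")
  expect_error(run_mcmc(d$plots[1:5, ], d$metrics[1:5, ], spec, config = cfg),
               "at least 10")
})

test_that("the null model recovers a constant mean within posterior uncertainty", {
  set.seed(12)
  n <- 40
  plots <- data.frame(x_km = runif(n, 0, 2), y_km = runif(n, 0, 2),
                      agb_sqrt = 5 + rnorm(n, 0, 0.3))
  fit <- run_mcmc(plots, spec = model_spec("null"),
                  config = mcmc_config(n_iter = 1500, n_burn = 500, thin = 2,
                                       seed = 2), recover_w = FALSE)
  b0 <- fit$samples$beta[, 1]
  expect_lt(abs(median(b0) - 5), 2 * sd(b0))
})

test_that("lidar covariates absorb most of the null model's spatial variance", {
  d <- tiny_dataset(120, seed = 31)
  cfg <- mcmc_config(n_iter = 1500, n_burn = 500, thin = 2, seed = 8)
  f_null <- run_mcmc(d$plots, spec = model_spec("null"), config = cfg,
                     recover_w = FALSE)
  f_cov <- run_mcmc(d$plots, d$metrics, model_spec("covariate", signal_metrics),
                    config = cfg, recover_w = FALSE)
  expect_gt(median(f_null$samples$sigma2), median(f_cov$samples$sigma2))
})
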