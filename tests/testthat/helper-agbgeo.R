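# Shared fixtures and independent oracles for the test suite.

# Dense-algebra multivariate normal log-density (naive inverse), used as the
# independent oracle for the marginalized likelihood.
naive_mvn_logdens <- function(y, mu, S) {
  n <- length(y)
  e <- y - mu
  -0.5 * (n * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus +
            drop(t(e) %*% solve(S) %*% e))
}

# Sort-based type-7 quantile oracle: linear interpolation between order
# statistics, written independently of stats::quantile.
sort_quantile_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Hand-built posterior "fit" object with fixed parameter draws, so
# composition sampling can be checked against closed-form kriging without
# running a chain.
make_fixed_fit <- function(coords, y, X, beta, sigma2, tau2, phi, w,
                           n_keep = 200L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  spec <- if (ncol(X) == 1L) model_spec("null") else
    model_spec("covariate", colnames(X)[-1])
  structure(list(
    samples = list(beta = matrix(rep(beta, each = n_keep), n_keep),
                   sigma2 = rep(sigma2, n_keep),
                   tau2 = rep(tau2, n_keep),
                   phi = rep(phi, n_keep),
                   eff_range_km = rep(effective_range(phi), n_keep),
                   w = matrix(rep(w, n_keep), n, n_keep)),
    acceptance_rate = NA_real_, spec = spec, priors = NULL,
    config = mcmc_config(seed = 1L),
    y = y, X = X, coords = coords, D = as.matrix(dist(coords)),
    n = n, n_keep = n_keep), class = "agbgeo_fit")
}

# Small clustered plot layout reused by several fit tests.
tiny_dataset <- function(n = 60L, seed = 11L) {
  generate_plot_dataset(sim_config(n_plots = n, domain_km = c(3, 3),
                                   seed = seed))
}

signal_metrics <- c("canopy_cover_pct", "mean_height_m", "rumple")
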