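# Bayesian geostatistical models for square-root AGB.
#
# Both models share the form
#   y(s) = x(s)' beta + w(s) + eps(s)
# where w(s) is a zero-mean Gaussian process with exponential covariance
# sigma2 * exp(-phi * d) and eps(s) is iid Normal(0, tau2). The null model
# keeps only the intercept (x(s) = 1). Sampling is done on the marginalized
# likelihood y ~ Normal(X beta, sigma2 R(phi) + tau2 I): a Gibbs update for
# beta (conjugate Gaussian) and an adaptive random-walk Metropolis update for
# (log sigma2, log tau2, logit-scaled phi). Spatial effects w are recovered
# per retained draw from their Gaussian full conditional.

#' Model specification for the geostatistical fit
#'
#' @param kind `"null"` (intercept only) or `"covariate"` (intercept plus the
#'   selected lidar metrics).
#' @param metric_names character vector of metric column names; must be empty
#'   for the null model and non-empty (typically the 3 selected metrics) for
#'   the covariate model.
#' @return an object of class `agbgeo_model_spec`.
#' @export
model_spec <- function(kind = c("covariate", "null"), metric_names = character()) {
  kind <- match.arg(kind)
  metric_names <- as.character(metric_names)
  if (kind == "null" && length(metric_names) > 0L) {
    stop("null model takes no metrics", call. = FALSE)
  }
  if (kind == "covariate" && length(metric_names) == 0L) {
    stop("covariate model requires metric names", call. = FALSE)
  }
  structure(list(kind = kind, metric_names = metric_names),
            class = "agbgeo_model_spec")
}

#' MCMC settings
#'
#' Defaults are sized for a full analysis run (25,000 iterations, 5,000
#' burn-in, thin 10, leaving 2,000 retained draws). Shorter chains are
#' adequate for the smaller synthetic studies in the package's tests and
#' examples.
#'
#' @param n_iter total iterations.
#' @param n_burn burn-in iterations discarded (must be < `n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param proposal_scale named numeric: random-walk standard deviations for
#'   `log_sigma2`, `log_tau2` and the logit-scaled `phi`.
#' @param adapt adapt the proposal scale during burn-in toward ~30%
#'   acceptance.
#' @param seed integer RNG seed; the chain is bit-reproducible given the seed.
#' @return an object of class `agbgeo_mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 25000L, n_burn = 5000L, thin = 10L,
                        proposal_scale = c(log_sigma2 = 0.4, log_tau2 = 0.8, phi = 0.5),
                        adapt = TRUE, seed = 1L) {
  n_iter <- as.integer(n_iter); n_burn <- as.integer(n_burn); thin <- as.integer(thin)
  if (n_burn >= n_iter) stop("n_burn must be < n_iter", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  ps <- proposal_scale[c("log_sigma2", "log_tau2", "phi")]
  if (any(is.na(ps)) || any(ps <= 0)) {
    stop("proposal_scale needs positive log_sigma2, log_tau2 and phi entries",
         call. = FALSE)
  }
  structure(list(n_iter = n_iter, n_burn = n_burn, thin = thin,
                 proposal_scale = ps, adapt = isTRUE(adapt),
                 seed = as.integer(seed)),
            class = "agbgeo_mcmc_config")
}

#' Vague default priors
#'
#' beta ~ Normal(0, 1e4) per coefficient; sigma2 and tau2 ~ inverse-gamma
#' with shape 2 and scale half the residual variance of an ordinary
#' least-squares fit of the response on the design (for the null model this
#' is simply half `var(y)`) - centering the variance priors on the scale
#' the model actually has to partition keeps them diffuse where the
#' posterior lives; phi ~ Uniform over the decay values whose effective
#' range spans the data's pairwise-distance range, with the minimum
#' distance floored at one grid cell width (0.03 km).
#'
#' @param y response vector (square-root AGB).
#' @param coords plot coordinates (km).
#' @param X design matrix (intercept plus metrics); `NULL` for intercept
#'   only.
#' @param d_floor_km lower floor for the minimum pairwise distance (km).
#' @return list of prior hyperparameters.
#' @export
default_priors <- function(y, coords, X = NULL, d_floor_km = 0.03) {
  d <- dist_matrix(coords)
  pos <- d[upper.tri(d)]
  pos <- pos[pos > 0]
  if (length(pos) == 0L) stop("all locations coincide", call. = FALSE)
  d_min <- max(min(pos), d_floor_km)
  d_max <- max(pos)
  res <- if (is.null(X)) y - mean(y) else qr.resid(qr(X), y)
  s2 <- 0.5 * sum(res^2) / (length(y) - 1)
  list(beta_mean = 0, beta_var = 1e4,
       sigma2_shape = 2, sigma2_scale = s2,
       tau2_shape = 2, tau2_scale = s2,
       phi_lower = -log(0.05) / d_max,
       phi_upper = -log(0.05) / d_min)
}

# log inverse-gamma density (shape a, scale b)
dinvgamma_log <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x

#' Nugget-to-sill ratio
#'
#' `tau2 / (tau2 + sigma2)`: the share of non-spatial variance in the total
#' sill. Values near 0 indicate strong spatial dependence.
#'
#' @param tau2 nugget variance(s), >= 0.
#' @param sigma2 partial sill(s), >= 0.
#' @return ratio in `[0, 1]`.
#' @export
nugget_to_sill <- function(tau2, sigma2) {
  if (any(tau2 < 0) || any(sigma2 < 0)) stop("variances must be >= 0", call. = FALSE)
  if (any(tau2 + sigma2 == 0)) stop("tau2 and sigma2 cannot both be zero", call. = FALSE)
  tau2 / (tau2 + sigma2)
}

# Build the design matrix for a model spec from a metric table.
build_design <- function(spec, metrics, n) {
  if (spec$kind == "null") {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    missing <- setdiff(spec$metric_names, colnames(metrics))
    if (length(missing)) {
      stop("metrics table lacks columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    M <- as.matrix(metrics[, spec$metric_names, drop = FALSE])
    if (!all(is.finite(M))) stop("non-finite metric values", call. = FALSE)
    X <- cbind("(Intercept)" = 1, M)
  }
  X
}

#' Fit a geostatistical model by MCMC
#'
#' Samples the posterior of (beta, sigma2, tau2, phi) under the marginalized
#' likelihood, then recovers the spatial effect w at the plot locations for
#' each retained draw. Exact duplicate locations are jittered by 1 m with a
#' warning (they make the marginal covariance singular as tau2 -> 0).
#'
#' @param plots data frame with columns `x_km`, `y_km` and `agb_sqrt` (or
#'   `agb_mg_ha`, from which the square root is taken).
#' @param metrics data frame of per-plot metric columns (row-aligned with
#'   `plots`); ignored for the null model.
#' @param spec a [model_spec()].
#' @param priors prior list as from [default_priors()]; `NULL` uses defaults.
#' @param config an [mcmc_config()].
#' @param recover_w draw the spatial effect at plot locations for every
#'   retained sample (needed for prediction; skip to save time when only
#'   parameter posteriors are of interest).
#' @return an object of class `agbgeo_fit`: retained draws (`beta`, `sigma2`,
#'   `tau2`, `phi`, `eff_range_km`, and `w` of dimension n x n_keep),
#'   acceptance rate, and the data needed for prediction.
#' @export
run_mcmc <- function(plots, metrics = NULL, spec = model_spec("null"),
                     priors = NULL, config = mcmc_config(), recover_w = TRUE) {
  stopifnot(inherits(spec, "agbgeo_model_spec"), inherits(config, "agbgeo_mcmc_config"))
  y <- if ("agb_sqrt" %in% names(plots)) plots$agb_sqrt else sqrt(plots$agb_mg_ha)
  n <- length(y)
  if (n < 10L) stop("need at least 10 plots", call. = FALSE)
  coords <- as_coord_matrix(plots)
  X <- build_design(spec, metrics, n)
  p <- ncol(X)
  if (n <= p + 1L) stop("too few plots for the design", call. = FALSE)

  # jitter exact duplicate locations by 1 m
  dup <- duplicated(coords)
  if (any(dup)) {
    warning(sprintf("%d duplicate plot location(s) jittered by 1 m", sum(dup)),
            call. = FALSE)
    set.seed(config$seed + 999L)
    coords[dup, ] <- coords[dup, ] + matrix(stats::rnorm(2 * sum(dup), 0, 0.001),
                                            ncol = 2)
  }
  D <- as.matrix(stats::dist(coords))
  if (is.null(priors)) priors <- default_priors(y, coords, X)
  plo <- priors$phi_lower; pup <- priors$phi_upper
  if (!(plo > 0 && pup > plo)) stop("phi prior bounds must be positive and ordered", call. = FALSE)

  beta_m0 <- rep(priors$beta_mean, length.out = p)
  V0_inv <- diag(1 / rep(priors$beta_var, length.out = p), p)

  set.seed(config$seed)
  # initial values: OLS for beta, residual variance split between sills
  qx <- qr(X)
  beta <- qr.coef(qx, y)
  v0 <- stats::var(qr.resid(qx, y))
  sigma2 <- 0.5 * v0
  tau2 <- 0.5 * v0
  phi <- sqrt(plo * pup)

  # working transforms: theta = (log sigma2, log tau2, logit((phi-lo)/(hi-lo)))
  to_logit <- function(x) log((x - plo) / (pup - x))
  from_logit <- function(z) plo + (pup - plo) * stats::plogis(z)
  theta <- c(log(sigma2), log(tau2), to_logit(phi))

  # Factor and prior/Jacobian terms depend only on theta; the quadratic form
  # also needs the residuals. Caching the factor lets the beta Gibbs step and
  # the post-update refresh reuse it without a second Cholesky per iteration.
  cov_state <- function(th) {
    s2 <- exp(th[1]); t2 <- exp(th[2]); ph <- from_logit(th[3])
    S <- s2 * exp(-ph * D)
    diag(S) <- diag(S) + t2
    U <- tryCatch(chol(S), error = function(err) NULL)
    if (is.null(U)) U <- chol_with_jitter(S, s2 + t2)
    ljp <- dinvgamma_log(s2, priors$sigma2_shape, priors$sigma2_scale) +
      dinvgamma_log(t2, priors$tau2_shape, priors$tau2_scale) +
      # Jacobians: log for the variances, logistic for phi
      th[1] + th[2] + log(ph - plo) + log(pup - ph) - log(pup - plo)
    list(U = U, ljp = ljp)
  }
  log_post <- function(st, e) {
    v <- backsolve(st$U, e, transpose = TRUE)
    -sum(log(diag(st$U))) - 0.5 * sum(v * v) + st$ljp
  }

  e <- y - X %*% beta
  cur <- cov_state(theta)
  cur_lp <- log_post(cur, e)
  if (!is.finite(cur_lp)) stop("divergent chain: non-finite initial log-posterior", call. = FALSE)

  keep_idx <- seq.int(config$n_burn + config$thin, config$n_iter, by = config$thin)
  n_keep <- length(keep_idx)
  out_beta <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  out_theta <- matrix(NA_real_, n_keep, 3L,
                      dimnames = list(NULL, c("sigma2", "tau2", "phi")))
  scale <- config$proposal_scale
  acc_total <- 0L; acc_batch <- 0L; batch_size <- 50L; batch_no <- 0L
  k <- 0L

  for (it in seq_len(config$n_iter)) {
    # Metropolis on the covariance parameters, conditional on beta
    prop <- theta + stats::rnorm(3L, 0, scale)
    cand <- cov_state(prop)
    cand_lp <- log_post(cand, e)
    if (is.finite(cand_lp) && log(stats::runif(1)) < cand_lp - cur_lp) {
      theta <- prop; cur <- cand; cur_lp <- cand_lp
      acc_total <- acc_total + 1L; acc_batch <- acc_batch + 1L
    }
    # Gibbs draw of beta given the covariance (reuses the cached factor)
    A <- backsolve(cur$U, X, transpose = TRUE)
    b <- backsolve(cur$U, y, transpose = TRUE)
    Vb_inv <- crossprod(A) + V0_inv
    Ub <- chol(Vb_inv)
    mb <- backsolve(Ub, backsolve(Ub, crossprod(A, b) + V0_inv %*% beta_m0,
                                  transpose = TRUE))
    beta <- drop(mb + backsolve(Ub, stats::rnorm(p)))
    e <- y - X %*% beta
    cur_lp <- log_post(cur, e)
    if (!is.finite(cur_lp)) stop("divergent chain: non-finite log-posterior", call. = FALSE)

    if (config$adapt && it <= config$n_burn && it %% batch_size == 0L) {
      batch_no <- batch_no + 1L
      rate <- acc_batch / batch_size
      scale <- scale * exp((rate - 0.3) / sqrt(batch_no))
      acc_batch <- 0L
    }

    if (it > config$n_burn && (it - config$n_burn) %% config$thin == 0L) {
      k <- k + 1L
      out_beta[k, ] <- beta
      out_theta[k, ] <- c(exp(theta[1]), exp(theta[2]), from_logit(theta[3]))
    }
  }

  acc_rate <- acc_total / config$n_iter
  if (acc_rate < 0.1 || acc_rate > 0.7) {
    warning(sprintf("Metropolis acceptance rate %.2f outside [0.1, 0.7]", acc_rate),
            call. = FALSE)
  }

  samples <- list(beta = out_beta,
                  sigma2 = out_theta[, "sigma2"],
                  tau2 = out_theta[, "tau2"],
                  phi = out_theta[, "phi"],
                  eff_range_km = effective_range(out_theta[, "phi"]))

  fit <- structure(list(samples = samples, acceptance_rate = acc_rate,
                        spec = spec, priors = priors, config = config,
                        y = y, X = X, coords = coords, D = D,
                        n = n, n_keep = n_keep),
                   class = "agbgeo_fit")
  if (recover_w) fit$samples$w <- recover_spatial_effects(fit)
  fit
}

# Spatial-effect full conditional, drawn once per retained sample:
#   w | y, beta, theta ~ Normal(K S^-1 e, K - K S^-1 K),  K = sigma2 R(phi),
#   S = K + tau2 I, e = y - X beta.
recover_spatial_effects <- function(fit) {
  s <- fit$samples
  n <- fit$n
  W <- matrix(NA_real_, n, fit$n_keep)
  set.seed(fit$config$seed + 1L)
  for (t in seq_len(fit$n_keep)) {
    K <- s$sigma2[t] * exp(-s$phi[t] * fit$D)
    S <- K
    diag(S) <- diag(S) + s$tau2[t]
    U <- chol_with_jitter(S, s$sigma2[t] + s$tau2[t])
    e <- fit$y - fit$X %*% s$beta[t, ]
    mean_w <- K %*% backsolve(U, backsolve(U, e, transpose = TRUE))
    B <- backsolve(U, K, transpose = TRUE)
    Cw <- K - crossprod(B)
    Uw <- chol_with_jitter((Cw + t(Cw)) / 2 + diag(1e-10 * s$sigma2[t], n),
                           s$sigma2[t])
    W[, t] <- mean_w + crossprod(Uw, stats::rnorm(n))
  }
  W
}

#' Posterior quantile summary
#'
#' Median and central 95% interval (2.5%, 97.5% quantiles) for every model
#' parameter, including the derived effective range in km.
#'
#' @param fit an `agbgeo_fit` (or a list of draw vectors/matrices).
#' @return data frame with columns `parameter`, `q50`, `q2.5`, `q97.5`.
#' @export
summarize_posterior <- function(fit) {
  s <- if (inherits(fit, "agbgeo_fit")) fit$samples else fit
  if (length(s$sigma2) < 100L) stop("need at least 100 retained draws", call. = FALSE)
  draws <- cbind(s$beta, sigma2 = s$sigma2, tau2 = s$tau2, phi = s$phi,
                 eff_range_km = s$eff_range_km)
  q <- t(apply(draws, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
               names = FALSE))
  data.frame(parameter = colnames(draws), q50 = q[, 1], q2.5 = q[, 2],
             q97.5 = q[, 3], row.names = NULL, check.names = FALSE)
}

#' @export
print.agbgeo_fit <- function(x, ...) {
  cat(sprintf("Bayesian geostatistical fit (%s model), n = %d plots\n",
              x$spec$kind, x$n))
  cat(sprintf("retained draws: %d; Metropolis acceptance: %.2f\n",
              x$n_keep, x$acceptance_rate))
  print(summarize_posterior(x), digits = 3)
  invisible(x)
}
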