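# Posterior predictive AGB at new locations by composition sampling.
#
# For each retained posterior draw (beta, sigma2, tau2, phi, w), the spatial
# effect at a new site is drawn from its Gaussian-process conditional given
# the w draw at the plot sites, then the sqrt-scale response adds the fixed
# part and nugget noise. Squaring the sqrt-scale draws gives the AGB-scale
# posterior predictive distribution; parameter uncertainty propagates
# because every draw uses its own parameters.

#' Composition-sample the posterior predictive distribution (sqrt scale)
#'
#' Per retained draw `t`: `w0 ~ Normal(r0' R^-1 w_t, sigma2_t (1 - r0' R^-1
#' r0))` with `R = exp(-phi_t d)` among plot sites and `r0` the plot-to-site
#' correlations, then `y0 = x0' beta_t + w0 + Normal(0, tau2_t)`. In
#' `"independent"` mode new sites are conditionally independent given each w
#' draw (tractable for large grids, slightly understates cross-pixel
#' dependence); `"joint"` mode draws all sites from the exact joint
#' conditional (limited to 2000 sites). All sites are processed in one
#' vectorized pass per draw in a fixed order, so results do not depend on
#' any blocking of the site list.
#'
#' @param fit an `agbgeo_fit` with recovered spatial effects (`recover_w =
#'   TRUE`).
#' @param new_coords coordinates of the prediction sites (km).
#' @param new_metrics metric table for the sites (covariate model); `NULL`
#'   for the null model. Missing values are an error.
#' @param seed RNG seed for the predictive draws.
#' @param mode `"independent"` (default) or `"joint"`.
#' @return matrix of sqrt-scale PPD draws, `n_keep` rows x sites columns.
#' @export
composition_predict <- function(fit, new_coords, new_metrics = NULL,
                                seed = 1L, mode = c("independent", "joint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "agbgeo_fit"))
  if (is.null(fit$samples$w)) {
    stop("fit lacks spatial-effect draws; rerun with recover_w = TRUE", call. = FALSE)
  }
  xy0 <- as_coord_matrix(new_coords)
  m <- nrow(xy0)
  if (mode == "joint" && m > 2000L) {
    stop("joint conditional mode is limited to 2000 sites", call. = FALSE)
  }
  X0 <- build_design(fit$spec, new_metrics, m)
  s <- fit$samples
  n <- fit$n
  Dcross <- sqrt(outer(fit$coords[, 1], xy0[, 1], `-`)^2 +
                 outer(fit$coords[, 2], xy0[, 2], `-`)^2)
  D00 <- if (mode == "joint") as.matrix(stats::dist(xy0)) else NULL

  set.seed(seed)
  out <- matrix(NA_real_, fit$n_keep, m)
  for (t in seq_len(fit$n_keep)) {
    R <- exp(-s$phi[t] * fit$D)
    diag(R) <- diag(R) + 1e-8
    U <- chol_with_jitter(R, 1)
    r0 <- exp(-s$phi[t] * Dcross)
    u <- backsolve(U, backsolve(U, s$w[, t], transpose = TRUE))
    mu_w <- drop(crossprod(r0, u))
    V <- backsolve(U, r0, transpose = TRUE)
    if (mode == "independent") {
      v_w <- pmax(0, s$sigma2[t] * (1 - colSums(V * V)))
      w0 <- mu_w + sqrt(v_w) * stats::rnorm(m)
    } else {
      C <- s$sigma2[t] * (exp(-s$phi[t] * D00) - crossprod(V))
      Uc <- chol_with_jitter((C + t(C)) / 2 + diag(1e-10 * s$sigma2[t], m),
                             s$sigma2[t])
      w0 <- mu_w + drop(crossprod(Uc, stats::rnorm(m)))
    }
    out[t, ] <- drop(X0 %*% s$beta[t, ]) + w0 +
      stats::rnorm(m, 0, sqrt(s$tau2[t]))
  }
  out
}

#' Back-transform sqrt-scale draws to AGB (Mg/ha)
#'
#' Elementwise square. Negative sqrt-scale draws are squared as-is: the
#' predictive distribution lives on the sqrt scale and squaring maps all of
#' it to the non-negative AGB scale.
#'
#' @param sqrt_draws numeric vector/matrix of sqrt-scale draws.
#' @return squared values with the same shape.
#' @export
back_transform <- function(sqrt_draws) {
  if (!all(is.finite(sqrt_draws))) stop("draws must be finite", call. = FALSE)
  sqrt_draws^2
}

#' Summarize AGB-scale PPDs per pixel
#'
#' Est is the PPD median (computed on the squared draws directly - the
#' square of the median is wrong once negative sqrt-scale draws exist), SD
#' the PPD standard deviation, RSD = 100 * SD / Est (undefined, NA, when
#' Est = 0), and the 95% interval the 2.5% and 97.5% quantiles.
#'
#' @param agb_draws matrix of AGB-scale draws, draws x pixels (>= 100
#'   draws).
#' @return data frame with `est`, `sd`, `rsd_pct`, `ci_lo`, `ci_hi` per
#'   pixel.
#' @export
summarize_pixels <- function(agb_draws) {
  agb_draws <- as.matrix(agb_draws)
  if (nrow(agb_draws) < 100L) stop("need at least 100 draws per pixel", call. = FALSE)
  est <- apply(agb_draws, 2L, stats::median)
  sdv <- apply(agb_draws, 2L, stats::sd)
  qs <- apply(agb_draws, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  data.frame(est = est, sd = sdv,
             rsd_pct = ifelse(est > 0, 100 * sdv / est, NA_real_),
             ci_lo = qs[1, ], ci_hi = qs[2, ])
}

#' Predict pixel-level AGB summaries for a metric grid
#'
#' Convenience wrapper: composition-sample the sqrt-scale PPD at the
#' unmasked grid cells, back-transform, and summarize. Masked cells get NA
#' rows.
#'
#' @param fit an `agbgeo_fit`.
#' @param grid data frame with `x_km`, `y_km`, metric columns and optional
#'   `mask_flag`.
#' @param seed RNG seed.
#' @param mode passed to [composition_predict()].
#' @return the grid with `est`, `sd`, `rsd_pct`, `ci_lo`, `ci_hi` appended.
#' @export
predict_agb <- function(fit, grid, seed = 1L, mode = "independent") {
  mask <- if ("mask_flag" %in% names(grid)) grid$mask_flag else rep(FALSE, nrow(grid))
  use <- !mask
  draws <- composition_predict(fit, grid[use, c("x_km", "y_km")],
                               new_metrics = grid[use, , drop = FALSE],
                               seed = seed, mode = mode)
  summ <- summarize_pixels(back_transform(draws))
  out <- grid
  for (cl in names(summ)) {
    out[[cl]] <- NA_real_
    out[[cl]][use] <- summ[[cl]]
  }
  out
}
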