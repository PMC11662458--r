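# Ten-fold holdout cross-validation and map-comparison error metrics.
#
# Conventions: RSE is the relative SQUARED error, 100 * sum((est-obs)^2) /
# sum((obs-mean(obs))^2) - a skill-free predictor centered on the
# observation mean scores near 100%. R^2 is the squared Pearson correlation
# of observed and estimated values. Point estimates are the back-transformed
# PPD medians.

#' Random k-fold assignment
#'
#' @param n_plots number of plots.
#' @param k number of folds (default 10); fold sizes differ by at most 1.
#' @param seed RNG seed.
#' @return integer fold label (1..k) per plot.
#' @export
kfold_split <- function(n_plots, k = 10L, seed = 1L) {
  if (k < 2L || k > n_plots) stop("need 2 <= k <= n_plots", call. = FALSE)
  set.seed(seed)
  sample(rep_len(seq_len(k), n_plots))
}

#' Validation metrics from observed values and interval predictions
#'
#' @param obs observed AGB (Mg/ha).
#' @param est predicted AGB point estimates (PPD medians, Mg/ha).
#' @param ci_lo,ci_hi 95% credible interval bounds (Mg/ha), ordered.
#' @param fold optional fold labels carried into the per-plot table.
#' @return object of class `agbgeo_validation`: `rmse`, `rse_pct`, `r2`,
#'   `bias`, `coverage_pct`, `mean_ci_width`, and a `per_plot` data frame
#'   with an `inside_ci` flag.
#' @export
compute_metrics <- function(obs, est, ci_lo, ci_hi, fold = NULL) {
  n <- length(obs)
  stopifnot(length(est) == n, length(ci_lo) == n, length(ci_hi) == n)
  if (any(ci_lo > ci_hi)) stop("credible intervals must be ordered", call. = FALSE)
  err <- est - obs
  sst <- sum((obs - mean(obs))^2)
  r2 <- if (sst == 0) {
    warning("constant observations: r2 undefined", call. = FALSE)
    NA_real_
  } else stats::cor(obs, est)^2
  inside <- obs >= ci_lo & obs <= ci_hi
  per_plot <- data.frame(obs = obs, est = est, ci_lo = ci_lo, ci_hi = ci_hi,
                         inside_ci = inside)
  if (!is.null(fold)) per_plot$fold <- fold
  structure(list(rmse = sqrt(mean(err^2)),
                 rse_pct = 100 * sum(err^2) / sst,
                 r2 = r2,
                 bias = mean(err),
                 coverage_pct = 100 * mean(inside),
                 mean_ci_width = mean(ci_hi - ci_lo),
                 n = n, per_plot = per_plot),
            class = "agbgeo_validation")
}

#' @export
print.agbgeo_validation <- function(x, ...) {
  cat(sprintf("holdout validation over %d plots\n", x$n))
  cat(sprintf("  RMSE %.2f Mg/ha | RSE %.2f%% | R2 %.2f | bias %.2f Mg/ha\n",
              x$rmse, x$rse_pct, x$r2, x$bias))
  cat(sprintf("  95%% coverage %.2f%% | mean CI width %.1f Mg/ha\n",
              x$coverage_pct, x$mean_ci_width))
  invisible(x)
}

#' Ten-fold cross-validation of a geostatistical model
#'
#' Plots are randomly split into `k` roughly equal folds; each fold is held
#' out in turn, the model is refit on the remainder, the holdout plots are
#' composition-predicted and back-transformed, and every plot ends up
#' predicted exactly once. Per-fold fit and prediction seeds derive
#' deterministically from `seed`.
#'
#' @param plots plot table (`x_km`, `y_km`, `agb_mg_ha`, `agb_sqrt`).
#' @param metrics metric table row-aligned with `plots` (ignored for the
#'   null model).
#' @param spec a [model_spec()].
#' @param config an [mcmc_config()]; its seed is re-derived per fold.
#' @param k number of folds.
#' @param seed seed controlling the fold split and per-fold chains.
#' @param priors prior list; `NULL` re-derives defaults on each training
#'   set.
#' @return `agbgeo_validation` report (the per-plot table carries folds).
#' @export
cv_run <- function(plots, metrics = NULL, spec = model_spec("null"),
                   config = mcmc_config(), k = 10L, seed = 1L, priors = NULL) {
  n <- nrow(plots)
  fold <- kfold_split(n, k, seed)
  est <- lo <- hi <- numeric(n)
  for (f in seq_len(k)) {
    hold <- fold == f
    cfg <- config
    cfg$seed <- as.integer((seed + 7919L * f) %% .Machine$integer.max)
    fit <- tryCatch(
      run_mcmc(plots[!hold, , drop = FALSE],
               metrics = if (is.null(metrics)) NULL else metrics[!hold, , drop = FALSE],
               spec = spec, priors = priors, config = cfg),
      error = function(e) stop("fold ", f, " fit failed: ", conditionMessage(e),
                               call. = FALSE))
    draws <- composition_predict(fit, plots[hold, c("x_km", "y_km")],
                                 new_metrics = if (is.null(metrics)) NULL else
                                   metrics[hold, , drop = FALSE],
                                 seed = cfg$seed + 1L)
    s <- summarize_pixels(back_transform(draws))
    est[hold] <- s$est; lo[hold] <- s$ci_lo; hi[hold] <- s$ci_hi
  }
  compute_metrics(plots$agb_mg_ha, est, lo, hi, fold = fold)
}

#' Compare plot observations against an external AGB map
#'
#' Error metrics for map values extracted at the plot locations, plus the
#' ordinary least squares line of predictions against observations
#' (prediction as the response): a slope below 1 is the signature of
#' regression toward the mean in the map.
#'
#' @param obs observed AGB (Mg/ha).
#' @param map_est map AGB values extracted at the plots (Mg/ha).
#' @return list: `rmse`, `rse_pct`, `bias`, `slope`, `intercept`, `n`.
#' @export
compare_to_map <- function(obs, map_est) {
  if (length(obs) != length(map_est)) stop("paired vectors required", call. = FALSE)
  if (length(obs) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(obs)) || !all(is.finite(map_est))) {
    stop("values must be finite", call. = FALSE)
  }
  err <- map_est - obs
  co <- stats::coef(stats::lm(map_est ~ obs))
  list(rmse = sqrt(mean(err^2)),
       rse_pct = 100 * sum(err^2) / sum((obs - mean(obs))^2),
       bias = mean(err),
       slope = unname(co[2]), intercept = unname(co[1]),
       n = length(obs))
}
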