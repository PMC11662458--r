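# Seeded synthetic data with the statistical structure the analysis assumes:
# clustered plot locations, a shared latent canopy-structure field that makes
# the three signal metrics inter-correlated and correlated with sqrt(AGB) at
# calibrated levels, a spatial random effect with exponential covariance, and
# an iid nugget. Everything downstream (selection, fitting, prediction,
# validation) is testable against the known truth.

# Metric naming shared across modules: 3 signal + 14 decoy = 17 candidates.
SIGNAL_METRICS <- c("canopy_cover_pct", "mean_height_m", "rumple")
DECOY_METRICS <- c("sd_height_m", paste0("p", sprintf("%02d", c(5, 10, 20, 25, 30, 40, 50, 60, 70, 75, 80, 90, 95))))

#' Names of the 17 candidate lidar metrics
#' @return character vector: canopy cover, mean height, rumple, height SD and
#'   the 13 height percentiles (5th-95th).
#' @export
metric_names_17 <- function() c(SIGNAL_METRICS, DECOY_METRICS)

# location and scale used to give simulated metrics realistic units
METRIC_MEAN <- c(canopy_cover_pct = 35, mean_height_m = 10, rumple = 2.2)
METRIC_SCALE <- c(canopy_cover_pct = 20, mean_height_m = 4.5, rumple = 0.9)
DECOY_MEAN <- stats::setNames(
  c(4, 3, 4, 4.5, 5, 6, 7.5, 9, 11, 12, 13, 15, 18, 20), DECOY_METRICS)
DECOY_SCALE <- stats::setNames(c(1.5, rep(4.5, 13)), DECOY_METRICS)

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the study conditions: 360 plots over a 10 x 10 km
#' domain, square-root-scale spatial variance parameters near the
#' covariate-model posterior medians (sigma2 = 4.2, tau2 = 0.72, effective
#' range 0.3 km), and three signal metrics whose correlations with
#' sqrt(AGB) are calibrated to 0.74 (canopy cover), 0.84 (mean height) and
#' 0.85 (rumple).
#'
#' @param n_plots number of plots.
#' @param domain_km width and height of the rectangular domain (km).
#' @param beta intercept and per-metric slopes on the sqrt(Mg/ha) scale, in
#'   the order (intercept, canopy cover, mean height, rumple).
#' @param sigma2 partial sill of the spatial effect (sqrt scale).
#' @param tau2 nugget variance (sqrt scale).
#' @param phi spatial decay of the residual effect (1/km).
#' @param phi_metric spatial decay of the shared latent structure field that
#'   drives the metrics (1/km); broader than `phi` so stand structure varies
#'   at landscape scale.
#' @param n_decoy_metrics number of decoy metrics (noisy mixtures of the
#'   signal metrics), up to 14.
#' @param target_correlations correlations of the three signal metrics with
#'   sqrt(AGB), each in (-1, 1).
#' @param plot_area_ha nominal plot area.
#' @param seed RNG seed; identical configs reproduce every value exactly.
#' @return an object of class `agbgeo_sim_config`.
#' @export
sim_config <- function(n_plots = 360L,
                       domain_km = c(10, 10),
                       beta = c(-1.45, 0.05, 0.42, 2.0),
                       sigma2 = 4.2, tau2 = 0.72, phi = 10,
                       phi_metric = 1.5,
                       n_decoy_metrics = 14L,
                       target_correlations = c(canopy_cover_pct = 0.74,
                                               mean_height_m = 0.84,
                                               rumple = 0.85),
                       plot_area_ha = 0.08,
                       seed = 42L) {
  if (n_plots < 1L) stop("n_plots must be >= 1", call. = FALSE)
  if (sigma2 < 0 || tau2 < 0) stop("sigma2 and tau2 must be >= 0", call. = FALSE)
  if (phi <= 0 || phi_metric <= 0) stop("spatial decay must be > 0", call. = FALSE)
  if (length(beta) != 4L) stop("beta must be (intercept, 3 slopes)", call. = FALSE)
  if (length(target_correlations) != 3L || any(abs(target_correlations) >= 1)) {
    stop("target correlations must be three values in (-1, 1)", call. = FALSE)
  }
  if (n_decoy_metrics < 0L || n_decoy_metrics > length(DECOY_METRICS)) {
    stop("n_decoy_metrics must be between 0 and 14", call. = FALSE)
  }
  structure(list(n_plots = as.integer(n_plots), domain_km = domain_km,
                 beta = beta, sigma2 = sigma2, tau2 = tau2, phi = phi,
                 phi_metric = phi_metric,
                 n_decoy_metrics = as.integer(n_decoy_metrics),
                 target_correlations = target_correlations,
                 plot_area_ha = plot_area_ha, seed = as.integer(seed)),
            class = "agbgeo_sim_config")
}

#' Draw a zero-mean Gaussian random field
#'
#' One realization of a zero-mean multivariate normal with covariance
#' `sigma2 * exp(-phi * d)` at the supplied locations, via Cholesky
#' factorization. Coincident locations receive identical values (the field
#' is simulated at the unique locations and copied).
#'
#' @param locations n x 2 matrix/data frame of coordinates (km).
#' @param sigma2 partial sill; 0 yields an all-zero field.
#' @param phi spatial decay (1/km).
#' @param seed RNG seed.
#' @return numeric vector of field values, one per location.
#' @export
simulate_gaussian_random_field <- function(locations, sigma2, phi, seed = 1L) {
  xy <- as_coord_matrix(locations)
  n <- nrow(xy)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (sigma2 == 0) return(rep(0, n))
  key <- paste(xy[, 1], xy[, 2], sep = "|")
  uniq <- !duplicated(key)
  xyu <- xy[uniq, , drop = FALSE]
  S <- exp_covariance(as.matrix(stats::dist(xyu)), sigma2, phi)
  U <- chol_with_jitter(S, sigma2)
  set.seed(seed)
  wu <- drop(crossprod(U, stats::rnorm(nrow(xyu))))
  wu[match(key, key[uniq])]
}

# Solve the loadings of the three signal metrics on the shared latent field
# so that cor(x_j, sqrt(AGB)) hits the targets. With z_j = a_j h +
# sqrt(1-a_j^2) eta_j and y = b0 + sum b_j z_j + w + eps (b_j = beta_j *
# scale_j), the target correlations give three coupled equations in the
# loadings a; they are solved numerically (no RNG involved).
solve_signal_loadings <- function(b, r, v_extra) {
  obj <- function(a) {
    A <- sum(a * b)
    V <- sum(b^2 * (1 - a^2)) + A^2 + v_extra
    rr <- (b * (1 - a^2) + a * A) / sqrt(V)
    sum((rr - r)^2)
  }
  o <- stats::optim(rep(0.8, 3), obj, method = "L-BFGS-B",
                    lower = 1e-6, upper = 1 - 1e-6,
                    control = list(factr = 1e4))
  if (o$value > 1e-8) {
    stop("unachievable target correlation for the given coefficients",
         call. = FALSE)
  }
  o$par
}

# Clustered plot locations: parent locations uniform over the domain, plots
# scattered around parents (normal offsets, sd 150 m), reflected at the
# domain boundary (reflection, unlike clamping, leaves no coincident plots).
# Mirrors field designs where several plots are measured per visited site.
cluster_locations <- function(n, domain_km) {
  reflect <- function(v, d) {
    v <- abs(v) %% (2 * d)
    ifelse(v > d, 2 * d - v, v)
  }
  n_parent <- max(1L, ceiling(n / 6))
  px <- stats::runif(n_parent, 0, domain_km[1])
  py <- stats::runif(n_parent, 0, domain_km[2])
  id <- sample.int(n_parent, n, replace = TRUE)
  x <- reflect(px[id] + stats::rnorm(n, 0, 0.15), domain_km[1])
  y <- reflect(py[id] + stats::rnorm(n, 0, 0.15), domain_km[2])
  cbind(x_km = x, y_km = y)
}

# Shared generative core: given locations (and a seeded RNG already set),
# return the metric table, sqrt response, and latent pieces.
generate_response_at <- function(config, xy) {
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  b <- config$beta[-1] * METRIC_SCALE
  alpha <- solve_signal_loadings(b, unname(config$target_correlations),
                                 config$sigma2 + config$tau2)
  # latent structure field (unit variance) and residual spatial effect
  Uh <- chol_with_jitter(exp(-config$phi_metric * D) + diag(1e-10, n), 1)
  h <- drop(crossprod(Uh, stats::rnorm(n)))
  w <- if (config$sigma2 > 0) {
    Uw <- chol_with_jitter(config$sigma2 * exp(-config$phi * D), config$sigma2)
    drop(crossprod(Uw, stats::rnorm(n)))
  } else rep(0, n)

  Z <- sapply(1:3, function(j) {
    alpha[j] * h + sqrt(1 - alpha[j]^2) * stats::rnorm(n)
  })
  X <- sweep(sweep(Z, 2, METRIC_SCALE, `*`), 2, METRIC_MEAN, `+`)
  colnames(X) <- SIGNAL_METRICS

  if (config$n_decoy_metrics > 0L) {
    dn <- DECOY_METRICS[seq_len(config$n_decoy_metrics)]
    Dm <- sapply(dn, function(nm) {
      u <- stats::runif(3)
      zd <- drop(Z %*% (u / sum(u))) + 0.6 * stats::rnorm(n)
      DECOY_MEAN[[nm]] + DECOY_SCALE[[nm]] * zd / stats::sd(zd)
    })
    X <- cbind(X, Dm)
  }

  eps <- stats::rnorm(n, 0, sqrt(config$tau2))
  y <- config$beta[1] + drop(X[, SIGNAL_METRICS] %*% config$beta[-1]) + w + eps
  list(metrics = as.data.frame(X), y_sqrt = y, w = w, h = h, alpha = alpha)
}

#' Generate a synthetic plot dataset
#'
#' Draws clustered plot locations, a shared latent structure field, the 17
#' candidate metrics (3 signal + up to 14 decoys), and the response
#' `sqrt(AGB) = beta0 + sum(beta x) + w + eps`. AGB is the square of the
#' sqrt-scale response; negative sqrt-scale draws are squared as-is (the
#' same convention the back-transform uses), never truncated.
#'
#' @param config a [sim_config()].
#' @return list of class `agbgeo_synthetic` with elements `plots` (plot
#'   table), `metrics` (17-column metric table, row-aligned), `truth`
#'   (config plus solved loadings) and `true_w` (latent spatial effect).
#' @export
generate_plot_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "agbgeo_sim_config"))
  set.seed(config$seed)
  xy <- cluster_locations(config$n_plots, config$domain_km)
  g <- generate_response_at(config, xy)
  agb <- g$y_sqrt^2
  plots <- data.frame(plot_id = sprintf("plot_%03d", seq_len(config$n_plots)),
                      x_km = xy[, "x_km"], y_km = xy[, "y_km"],
                      area_ha = config$plot_area_ha,
                      agb_mg_ha = agb, agb_sqrt = g$y_sqrt,
                      dataset_tag = "synthetic", year = 2020L)
  structure(list(plots = plots, metrics = g$metrics,
                 truth = c(config, list(alpha = g$alpha)),
                 true_w = g$w),
            class = "agbgeo_synthetic")
}

#' Generate a synthetic 30 m pixel grid (optionally with co-located plots)
#'
#' Pixel centers over a rectangular extent share the plot-level generative
#' process; when `n_plots > 0`, plots are drawn inside the same extent and
#' the latent fields are simulated jointly over plots and pixels, so
#' model-based predictions of the grid can be checked against the simulated
#' truth. The grid is split into `n_mu` vertical management-unit strips.
#'
#' @param config a [sim_config()]; `domain_km` is ignored in favor of
#'   `extent_km`.
#' @param extent_km width and height of the gridded extent (km); must span
#'   at least 2 x 2 cells.
#' @param cell_size_m cell size in meters (default 30).
#' @param n_mu number of management-unit strips (>= 2).
#' @param n_plots number of plots to co-generate (0 for grid only).
#' @return list of class `agbgeo_synthetic_grid` with `grid` (cell table:
#'   id, center coordinates, 17 metrics, `agb_true_mg_ha`, `mu`,
#'   `mask_flag`), and when plots are requested, `plots`, `metrics` and
#'   `true_w` for the plot subset.
#' @export
generate_pixel_grid <- function(config = sim_config(), extent_km = c(1.5, 1.5),
                                cell_size_m = 30, n_mu = 2L, n_plots = 0L) {
  stopifnot(inherits(config, "agbgeo_sim_config"))
  if (cell_size_m <= 0) stop("cell size must be > 0", call. = FALSE)
  cs <- cell_size_m / 1000
  nx <- floor(extent_km[1] / cs)
  ny <- floor(extent_km[2] / cs)
  if (nx < 2L || ny < 2L) stop("extent must span at least 2 x 2 cells", call. = FALSE)
  cx <- (seq_len(nx) - 0.5) * cs
  cy <- (seq_len(ny) - 0.5) * cs
  cells <- expand.grid(x_km = cx, y_km = cy, KEEP.OUT.ATTRS = FALSE)
  n_cell <- nrow(cells)

  set.seed(config$seed)
  if (n_plots > 0L) {
    pxy <- cluster_locations(n_plots, c(nx * cs, ny * cs))
    xy <- rbind(as.matrix(cells), pxy)
  } else {
    xy <- as.matrix(cells)
  }
  g <- generate_response_at(config, xy)

  mu_labels <- paste0("MU_", LETTERS[seq_len(n_mu)])
  mu <- mu_labels[pmin(n_mu, 1L + floor(cells$x_km / (nx * cs) * n_mu))]
  grid <- data.frame(cell_id = seq_len(n_cell),
                     x_km = cells$x_km, y_km = cells$y_km,
                     g$metrics[seq_len(n_cell), , drop = FALSE],
                     agb_true_mg_ha = g$y_sqrt[seq_len(n_cell)]^2,
                     mu = mu, mask_flag = FALSE,
                     row.names = NULL)
  out <- list(grid = grid, cell_size_m = cell_size_m,
              truth = c(config, list(alpha = g$alpha)))
  if (n_plots > 0L) {
    idx <- n_cell + seq_len(n_plots)
    ysq <- g$y_sqrt[idx]
    out$plots <- data.frame(plot_id = sprintf("plot_%03d", seq_len(n_plots)),
                            x_km = xy[idx, 1], y_km = xy[idx, 2],
                            area_ha = config$plot_area_ha,
                            agb_mg_ha = ysq^2, agb_sqrt = ysq,
                            dataset_tag = "synthetic", year = 2020L)
    out$metrics <- g$metrics[idx, , drop = FALSE]
    rownames(out$metrics) <- NULL
    out$true_w <- g$w[idx]
  }
  structure(out, class = "agbgeo_synthetic_grid")
}

#' Generate a synthetic tree list for one plot
#'
#' Trees are drawn with lognormal DBH above the 7.6 cm threshold until their
#' allometric AGB reaches the target plot density; the last tree is sized to
#' close the mass budget exactly. The list also carries one sub-threshold
#' tree and one cluster record (count 2) so aggregation filters and cluster
#' expansion are exercised.
#'
#' @param target_agb_mg_ha target AGB density (>= 0).
#' @param plot_area_ha plot area (> 0).
#' @param allometry power-law `c(a, b)` used for `agb_kg = a * dbh^b`.
#' @param seed RNG seed.
#' @return data frame of tree records (`species`, `dbh_cm`, `height_m`,
#'   `status`, `agb_kg`, `cluster_count`).
#' @export
generate_tree_list <- function(target_agb_mg_ha, plot_area_ha = 0.08,
                               allometry = c(a = 0.08, b = 2.4), seed = 1L) {
  if (target_agb_mg_ha < 0) stop("target AGB must be >= 0", call. = FALSE)
  if (plot_area_ha <= 0) stop("plot area must be > 0", call. = FALSE)
  a <- allometry[[1]]; bb <- allometry[[2]]
  set.seed(seed)
  target_kg <- target_agb_mg_ha * plot_area_ha * 1000
  dbh <- numeric(); cluster <- integer()
  mass <- function() sum(a * dbh^bb * cluster)
  while (length(dbh) == 0L || mass() < 0.97 * target_kg) {
    if (target_kg == 0) break
    d <- max(7.6, stats::rlnorm(1, log(16), 0.45))
    k <- if (length(dbh) == 0L) 2L else 1L  # first record is a 2-stem cluster
    if (mass() + a * d^bb * k > target_kg) {
      # size the closing tree to the remaining budget
      rem <- (target_kg - mass()) / k
      d <- (rem / a)^(1 / bb)
      if (d < 7.6) break
    }
    dbh <- c(dbh, d); cluster <- c(cluster, k)
  }
  rem <- target_kg - mass()
  if (rem > 0 && length(dbh) > 0L) {
    # fold any residual into the largest tree so the budget closes exactly
    i <- which.max(dbh)
    dbh[i] <- ((a * dbh[i]^bb + rem / cluster[i]) / a)^(1 / bb)
  }
  n <- length(dbh)
  status <- if (n > 0) ifelse(stats::runif(n) < 0.15, "dead", "live") else character()
  trees <- data.frame(species = rep("PIAL", n), dbh_cm = dbh,
                      height_m = 1.37 + 0.6 * dbh, status = status,
                      agb_kg = a * dbh^bb, cluster_count = cluster)
  # one sub-threshold tree, excluded by the DBH filter
  small <- data.frame(species = "PIAL", dbh_cm = 5.0, height_m = 4.4,
                      status = "live", agb_kg = a * 5.0^bb, cluster_count = 1L)
  rbind(trees, small)
}

#' Generate a synthetic normalized point cloud for one cell
#'
#' Points are placed uniformly in plan over a square cell; a rounded
#' `target_cover_pct` share of them get heights drawn around
#' `target_mean_height_m` (above the 2 m canopy threshold), the rest get
#' heights in (0, 2) m.
#'
#' @param target_cover_pct canopy cover target in percent (0-100).
#' @param target_mean_height_m mean height of above-2 m points (> 2 when
#'   cover > 0).
#' @param n_points number of points (>= 1).
#' @param cell_size_m cell edge length in meters.
#' @param height_sd_m spread of the above-2 m heights; 0 gives constant
#'   heights.
#' @param seed RNG seed.
#' @return data frame with columns `x`, `y`, `z` (meters; z normalized
#'   above ground).
#' @export
generate_point_cloud <- function(target_cover_pct, target_mean_height_m,
                                 n_points = 1000L, cell_size_m = 30,
                                 height_sd_m = 1.5, seed = 1L) {
  if (n_points < 1L) stop("n_points must be >= 1", call. = FALSE)
  if (target_cover_pct < 0 || target_cover_pct > 100) {
    stop("cover must be in [0, 100]", call. = FALSE)
  }
  if (target_cover_pct > 0 && target_mean_height_m <= 2) {
    stop("mean height must exceed the 2 m canopy threshold", call. = FALSE)
  }
  set.seed(seed)
  n_above <- round(n_points * target_cover_pct / 100)
  z_above <- if (n_above > 0) {
    z <- stats::rnorm(n_above, target_mean_height_m, height_sd_m)
    while (any(z <= 2)) z[z <= 2] <- stats::rnorm(sum(z <= 2), target_mean_height_m, height_sd_m)
    z
  } else numeric()
  z_below <- stats::runif(n_points - n_above, 0, 2)
  z <- sample(c(z_above, z_below))
  data.frame(x = stats::runif(n_points, 0, cell_size_m),
             y = stats::runif(n_points, 0, cell_size_m),
             z = z)
}
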