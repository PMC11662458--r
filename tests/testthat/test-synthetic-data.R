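test_that("gaussian random field honors the zero-variance and coincident-location limits", {
  locs <- cbind(c(0, 0.5, 1, 0), c(0, 0.2, 1, 0))
  expect_equal(simulate_gaussian_random_field(locs, 0, 5, seed = 3),
               rep(0, 4))
  w <- simulate_gaussian_random_field(locs, 2, 5, seed = 3)
  expect_identical(w[1], w[4])  # coincident locations share the field value
  expect_identical(w, simulate_gaussian_random_field(locs, 2, 5, seed = 3))
  expect_error(simulate_gaussian_random_field(cbind(NA, 1), 1, 1), "finite")
})

test_that("repeated field draws reproduce the closed-form exponential covariance", {
  locs <- cbind(c(0, 0.2), c(0, 0))
  draws <- t(sapply(1:500, function(i) {
    simulate_gaussian_random_field(locs, sigma2 = 4, phi = 5, seed = 5000 + i)
  }))
  sample_cov <- cov(draws)[1, 2]
  # truth 4 * exp(-1) = 1.4715; Monte-Carlo sd of the sample covariance is
  # about sqrt((s11 s22 + s12^2)/n) ~ 0.19, so 3 sigma ~ 0.58
  expect_lt(abs(sample_cov - 4 * exp(-1)), 0.58)
  expect_equal(unname(diag(cov(draws))), c(4, 4), tolerance = 0.3)
})

test_that("plot dataset is seed-deterministic and squares its sqrt response", {
  d1 <- generate_plot_dataset(sim_config(n_plots = 80, seed = 9))
  d2 <- generate_plot_dataset(sim_config(n_plots = 80, seed = 9))
  expect_identical(d1, d2)
  expect_identical(d1$plots$agb_mg_ha, d1$plots$agb_sqrt^2)
  expect_true(all(d1$plots$agb_mg_ha >= 0))
  expect_identical(nrow(d1$metrics), nrow(d1$plots))
  expect_identical(ncol(d1$metrics), 17L)
})

test_that("noiseless generator reproduces AGB exactly from the linear predictor", {
  cfg <- sim_config(n_plots = 40, sigma2 = 0, tau2 = 0, seed = 2)
  d <- generate_plot_dataset(cfg)
  lin <- cfg$beta[1] + as.matrix(d$metrics[, signal_metrics]) %*% cfg$beta[-1]
  expect_equal(d$plots$agb_mg_ha, unname(drop(lin))^2, tolerance = 1e-12)
})

test_that("signal-metric correlations with sqrt AGB hit the calibrated targets", {
  d <- generate_plot_dataset(sim_config())
  r <- cor(d$metrics[, signal_metrics], d$plots$agb_sqrt)
  expect_equal(drop(r), c(0.74, 0.84, 0.85), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("unachievable correlation targets are rejected", {
  expect_error(sim_config(target_correlations = c(1.0, 0.8, 0.8)), "-1, 1")
  cfg <- sim_config(target_correlations = c(0.99, 0.99, 0.99),
                    beta = c(0, 0.001, 0.001, 0.001))
  expect_error(generate_plot_dataset(cfg), "unachievable")
})

test_that("pixel grid is deterministic, collapses under zero variance, and averages exactly", {
  cfg0 <- sim_config(sigma2 = 0, tau2 = 0, seed = 4)
  g0 <- generate_pixel_grid(cfg0, extent_km = c(0.06, 0.06), cell_size_m = 30)
  # 2 x 2 grid; with both variance terms off, every cell's true AGB is an
  # exact deterministic function of its metrics
  expect_equal(nrow(g0$grid), 4L)
  lin0 <- cfg0$beta[1] +
    as.matrix(g0$grid[, signal_metrics]) %*% cfg0$beta[-1]
  expect_equal(g0$grid$agb_true_mg_ha, unname(drop(lin0))^2, tolerance = 1e-12)

  g1 <- generate_pixel_grid(sim_config(seed = 6), extent_km = c(1.5, 1.5))
  g2 <- generate_pixel_grid(sim_config(seed = 6), extent_km = c(1.5, 1.5))
  expect_identical(g1, g2)
  expect_gte(length(unique(g1$grid$mu)), 2L)
  for (id in unique(g1$grid$mu)) {
    sel <- g1$grid$mu == id
    expect_equal(mean(g1$grid$agb_true_mg_ha[sel]),
                 sum(g1$grid$agb_true_mg_ha[sel]) / sum(sel))
  }
  expect_error(generate_pixel_grid(sim_config(), extent_km = c(0.03, 1)),
               "2 x 2")
  expect_error(generate_pixel_grid(sim_config(), cell_size_m = 0), "> 0")
})

test_that("tree lists close the mass budget and carry filter-exercising records", {
  tl <- generate_tree_list(100, plot_area_ha = 0.1, seed = 21)
  expect_identical(tl, generate_tree_list(100, plot_area_ha = 0.1, seed = 21))
  expect_true(any(tl$dbh_cm < 7.6))        # sub-threshold tree present
  expect_true(any(tl$cluster_count > 1L))  # cluster record present
  agb <- aggregate_plot_agb(tl, area_ha = 0.1)
  expect_lt(abs(agb - 100) / 100, 0.005)

  tl0 <- generate_tree_list(0, plot_area_ha = 0.1, seed = 3)
  expect_equal(aggregate_plot_agb(tl0, area_ha = 0.1), 0)
  expect_error(generate_tree_list(-5, 0.1), ">= 0")
})

test_that("point clouds meet their cover and height targets", {
  pc <- generate_point_cloud(100, 10, n_points = 500, height_sd_m = 0, seed = 1)
  expect_equal(pc$z, rep(10, 500))
  pc0 <- generate_point_cloud(0, 10, n_points = 200, seed = 2)
  expect_true(all(pc0$z <= 2))
  pc50 <- generate_point_cloud(50, 12, n_points = 1000, seed = 3)
  expect_equal(100 * mean(pc50$z > 2), 50, tolerance = 0.2)
  expect_error(generate_point_cloud(50, 12, n_points = 0), ">= 1")
  expect_error(generate_point_cloud(50, 1.5), "2 m")
})
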