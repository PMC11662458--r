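# Closed-form kriging oracle: prediction mean/variance at new sites given
# fixed (beta, sigma2, tau2, phi, w), via dense inverses.
krig_oracle <- function(coords, site, w, sigma2, phi) {
  R <- exp(-phi * as.matrix(dist(coords)))
  r0 <- exp(-phi * sqrt((coords[, 1] - site[1])^2 + (coords[, 2] - site[2])^2))
  list(mean = drop(r0 %*% solve(R, w)),
       var = sigma2 * (1 - drop(r0 %*% solve(R, r0))))
}

test_that("composition draws match closed-form kriging at a new site", {
  coords <- rbind(c(0, 0), c(0.4, 0.1), c(0.2, 0.5))
  w <- c(0.9, -0.4, 0.2)
  X <- cbind(1, c(10, 20, 15)); colnames(X) <- c("(Intercept)", "m")
  beta <- c(0.5, 0.1); sigma2 <- 2; tau2 <- 0.3; phi <- 3
  fit <- make_fixed_fit(coords, y = drop(X %*% beta) + w, X = X, beta = beta,
                        sigma2 = sigma2, tau2 = tau2, phi = phi, w = w,
                        n_keep = 6000L)
  site <- c(0.25, 0.2)
  dr <- composition_predict(fit, rbind(site), data.frame(m = 12), seed = 4)
  or <- krig_oracle(coords, site, w, sigma2, phi)
  mu0 <- 0.5 + 0.1 * 12 + or$mean
  expect_equal(mean(dr), mu0, tolerance = 4 * sqrt((or$var + tau2) / 6000))
  expect_equal(var(drop(dr)), or$var + tau2, tolerance = 0.1 * (or$var + tau2))
})

test_that("a coincident site with zero nugget interpolates the plot exactly", {
  coords <- rbind(c(0, 0), c(1, 0), c(0.5, 1))
  w <- c(1.2, -0.5, 0.3)
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- make_fixed_fit(coords, y = 5 + w, X = X, beta = 5, sigma2 = 1.5,
                        tau2 = 0, phi = 2, w = w, n_keep = 150L)
  dr <- composition_predict(fit, rbind(c(0, 0)), seed = 1)
  expect_equal(drop(dr), rep(5 + w[1], 150), tolerance = 1e-3)
})

test_that("far beyond the effective range the predictive variance is the full sill", {
  coords <- rbind(c(0, 0), c(0.3, 0), c(0, 0.3))
  w <- c(0.4, -0.2, 0.1)
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  sigma2 <- 2; tau2 <- 0.5
  fit <- make_fixed_fit(coords, y = 3 + w, X = X, beta = 3, sigma2 = sigma2,
                        tau2 = tau2, phi = 5, w = w, n_keep = 6000L)
  dr <- composition_predict(fit, rbind(c(50, 50)), seed = 2)
  expect_equal(mean(dr), 3, tolerance = 4 * sqrt((sigma2 + tau2) / 6000))
  expect_equal(var(drop(dr)), sigma2 + tau2,
               tolerance = 0.1 * (sigma2 + tau2))
})

test_that("joint and independent modes agree marginally and are seed-stable", {
  coords <- rbind(c(0, 0), c(0.4, 0.1), c(0.2, 0.5), c(0.6, 0.6))
  w <- c(0.9, -0.4, 0.2, 0.1)
  X <- matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- make_fixed_fit(coords, y = 2 + w, X = X, beta = 2, sigma2 = 1.2,
                        tau2 = 0.2, phi = 3, w = w, n_keep = 4000L)
  sites <- rbind(c(0.3, 0.3), c(0.1, 0.4))
  d_ind <- composition_predict(fit, sites, seed = 9, mode = "independent")
  d_joint <- composition_predict(fit, sites, seed = 9, mode = "joint")
  expect_equal(colMeans(d_ind), colMeans(d_joint), tolerance = 0.05)
  expect_equal(apply(d_ind, 2, var), apply(d_joint, 2, var), tolerance = 0.1)
  expect_identical(d_ind,
                   composition_predict(fit, sites, seed = 9, mode = "independent"))
})

test_that("back-transform squares draws elementwise and obeys Jensen's inequality", {
  expect_equal(back_transform(c(-1, 0, 2)), c(1, 0, 4))
  expect_equal(back_transform(rep(0, 5)), rep(0, 5))
  set.seed(3)
  x <- rnorm(500, 1, 2)
  expect_gte(mean(back_transform(x)), mean(x)^2)
  expect_error(back_transform(c(1, NA)), "finite")
})

test_that("pixel summaries match their sort-based quantile oracle", {
  const <- matrix(100, 200, 1)
  s <- summarize_pixels(const)
  expect_equal(unlist(s[1, ]), c(est = 100, sd = 0, rsd_pct = 0,
                                 ci_lo = 100, ci_hi = 100))
  set.seed(5)
  dr <- matrix(rgamma(1001 * 2, 4, 0.05), 1001, 2)
  s2 <- summarize_pixels(dr)
  for (j in 1:2) {
    expect_equal(s2$est[j], sort_quantile_oracle(dr[, j], 0.5))
    expect_equal(s2$ci_lo[j], sort_quantile_oracle(dr[, j], 0.025))
    expect_equal(s2$ci_hi[j], sort_quantile_oracle(dr[, j], 0.975))
    expect_equal(s2$rsd_pct[j], 100 * sd(dr[, j]) / s2$est[j])
  }
  zero <- matrix(0, 150, 1)
  expect_true(is.na(summarize_pixels(zero)$rsd_pct))
  expect_error(summarize_pixels(matrix(1, 50, 1)), "100 draws")
})

test_that("predictive spread grows with distance from the plots", {
  set.seed(6)
  n <- 30
  coords <- cbind(runif(n, 0, 0.5), runif(n, 0, 0.5))
  w <- drop(crossprod(chol(1.5 * exp(-4 * as.matrix(dist(coords))) +
                             diag(1e-8, n)), rnorm(n)))
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- make_fixed_fit(coords, y = 8 + w, X = X, beta = 8, sigma2 = 1.5,
                        tau2 = 0.2, phi = 4, w = w, n_keep = 800L)
  # homogeneous sites marching away from the sampled square
  sites <- cbind(seq(0.25, 1.2, length.out = 12), 0.25)
  dr <- composition_predict(fit, sites, seed = 8)
  sds <- apply(dr, 2, sd)
  bins <- colMeans(matrix(sds, nrow = 4))  # 3 distance bins of 4 sites
  expect_gt(bins[2], bins[1])
  expect_gt(bins[3], bins[1])
})

test_that("grid prediction skips masked cells", {
  coords <- rbind(c(0, 0), c(0.2, 0.1), c(0.1, 0.3))
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- make_fixed_fit(coords, y = c(5, 5.5, 4.5), X = X, beta = 5,
                        sigma2 = 1, tau2 = 0.2, phi = 3,
                        w = c(0, 0.5, -0.5), n_keep = 120L)
  grid <- data.frame(x_km = c(0.1, 0.15), y_km = c(0.1, 0.2),
                     mask_flag = c(FALSE, TRUE))
  out <- predict_agb(fit, grid, seed = 1)
  expect_false(is.na(out$est[1]))
  expect_true(is.na(out$est[2]))
  expect_true(out$ci_lo[1] <= out$est[1] && out$est[1] <= out$ci_hi[1])
})
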