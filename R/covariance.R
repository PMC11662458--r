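# Exponential covariance kernel and marginalized Gaussian likelihood.
# All distances are Euclidean and in kilometres.

#' Pairwise Euclidean distance matrix
#'
#' @param coords two-column matrix or data frame of projected coordinates
#'   (km): columns `x_km`, `y_km` or the first two columns.
#' @return symmetric n x n distance matrix (km) with zero diagonal.
#' @export
dist_matrix <- function(coords) {
  xy <- as_coord_matrix(coords)
  as.matrix(stats::dist(xy))
}

as_coord_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    if (all(c("x_km", "y_km") %in% names(coords))) {
      coords <- coords[, c("x_km", "y_km")]
    }
    coords <- as.matrix(coords)
  }
  if (!is.numeric(coords) || ncol(coords) != 2L) {
    stop("coordinates must be a numeric matrix with two columns", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  unname(coords)
}

#' Exponential spatial covariance
#'
#' `sigma2 * exp(-phi * d)`: the stationary covariance of the spatial random
#' effect. At distance zero it equals the partial sill `sigma2`; at the
#' effective range `-log(0.05)/phi` it has decayed to `0.05 * sigma2`.
#'
#' @param d distance matrix (km), symmetric with zero diagonal, or any
#'   non-negative numeric array of distances.
#' @param sigma2 partial sill (variance of the spatial effect), >= 0.
#' @param phi spatial decay (1/km), > 0.
#' @return covariance values with the shape of `d`.
#' @export
exp_covariance <- function(d, sigma2, phi) {
  stopifnot(is.numeric(d), length(sigma2) == 1L, length(phi) == 1L)
  if (any(d < 0)) stop("negative distances", call. = FALSE)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (phi <= 0) stop("phi must be > 0", call. = FALSE)
  sigma2 * exp(-phi * d)
}

#' Effective range of the exponential covariance
#'
#' Distance at which the correlation between two locations falls to 0.05,
#' i.e. `-log(0.05)/phi` (about `2.9957/phi`) km.
#'
#' @param phi spatial decay (1/km), > 0.
#' @return effective range in km.
#' @export
effective_range <- function(phi) {
  if (any(phi <= 0)) stop("phi must be > 0", call. = FALSE)
  -log(0.05) / phi
}

# Cholesky with a logged jitter fallback: on failure add 1e-8 * sigma2 to the
# diagonal once. Returns the upper-triangular factor.
chol_with_jitter <- function(S, sigma2 = mean(diag(S))) {
  U <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(U)) {
    jit <- 1e-8 * sigma2
    warning(sprintf("covariance factorization failed; retrying with %.3g jitter on the diagonal", jit),
            call. = FALSE)
    U <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) {
      stop("covariance factorization failed even after 1e-8*sigma2 diagonal jitter",
           call. = FALSE)
    })
  }
  U
}

#' Marginalized Gaussian log-likelihood of the geostatistical model
#'
#' With the spatial effect integrated out, the square-root-scale response is
#' `y ~ Normal(X beta, sigma2 * R(phi) + tau2 * I)` where `R(phi)` is the
#' exponential correlation matrix. Evaluated through a Cholesky
#' factorization.
#'
#' @param y numeric response vector (square-root AGB scale).
#' @param X design matrix (with intercept column); `NULL` means a zero mean.
#' @param beta coefficient vector matching `X`.
#' @param sigma2,tau2 partial sill and nugget variances.
#' @param phi spatial decay (1/km).
#' @param d distance matrix among the observation locations (km).
#' @return the log-density (scalar).
#' @export
log_marginal_likelihood <- function(y, X, beta, sigma2, tau2, phi, d) {
  n <- length(y)
  mu <- if (is.null(X)) rep(0, n) else as.vector(X %*% beta)
  S <- exp_covariance(d, sigma2, phi)
  diag(S) <- diag(S) + tau2
  U <- chol_with_jitter(S, sigma2 + tau2)
  e <- y - mu
  v <- backsolve(U, e, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(v * v)
}
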