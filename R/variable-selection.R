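# Exhaustive screening of 2- and 3-metric OLS models for sqrt(AGB).
#
# All C(m,2) + C(m,3) subsets of the candidate metrics are fit by ordinary
# least squares with an intercept and ranked by adjusted R^2 (descending),
# with ties broken by lower AIC, then smaller subset, then lexicographic
# names. Collinearity among selected metrics is allowed.

#' Enumerate all 2- and 3-metric candidate subsets
#'
#' @param metric_names character vector of at least 3 distinct metric names.
#' @return list of character vectors (all size-2 subsets, then all size-3),
#'   in deterministic lexicographic order regardless of input order.
#' @export
enumerate_candidates <- function(metric_names) {
  if (anyDuplicated(metric_names)) stop("duplicate metric names", call. = FALSE)
  if (length(metric_names) < 3L) stop("need at least 3 metrics", call. = FALSE)
  nm <- sort(metric_names)
  c(utils::combn(nm, 2L, simplify = FALSE),
    utils::combn(nm, 3L, simplify = FALSE))
}

#' Ordinary least squares fit with adjusted R^2 and AIC
#'
#' Gaussian AIC uses the maximum-likelihood error variance (RSS/n) and
#' counts the intercept, the slopes, and the variance as parameters:
#' `AIC = -2 logL + 2 (p + 2)` for `p` predictors. Only relative ranking
#' matters.
#'
#' @param y response vector (square-root AGB).
#' @param X predictor matrix (no intercept column; one is added).
#' @return list with `coefficients`, `r2`, `adj_r2`, `aic`, `n`, `p`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (n <= p + 1L) stop("need n > p + 1 observations", call. = FALSE)
  Xi <- cbind("(Intercept)" = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qx$pivot[seq.int(qx$rank + 1L, ncol(Xi))]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  loglik <- -0.5 * n * (log(2 * pi) + log(rss / n) + 1)
  aic <- -2 * loglik + 2 * (p + 2)
  list(coefficients = coef, r2 = r2, adj_r2 = adj_r2, aic = aic, n = n, p = p)
}

#' Fit and rank all 2- and 3-metric candidate models
#'
#' @param y_sqrt square-root AGB response for the (unmasked) plots.
#' @param metrics data frame of candidate metric columns, row-aligned with
#'   `y_sqrt`; no missing values.
#' @return object of class `agbgeo_selection`: a ranking data frame
#'   (`subset`, `size`, `r2`, `adj_r2`, `aic`, `rank`) with the winning
#'   metric names in `$best`.
#' @export
select_best <- function(y_sqrt, metrics) {
  if (anyNA(metrics)) stop("missing metric values", call. = FALSE)
  cands <- enumerate_candidates(colnames(metrics))
  rows <- lapply(cands, function(sub) {
    f <- tryCatch(fit_ols(y_sqrt, metrics[, sub, drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(f)) {
      return(data.frame(subset = paste(sub, collapse = ","),
                        size = length(sub), r2 = NA_real_,
                        adj_r2 = NA_real_, aic = NA_real_, failed = TRUE))
    }
    data.frame(subset = paste(sub, collapse = ","), size = length(sub),
               r2 = f$r2, adj_r2 = f$adj_r2, aic = f$aic, failed = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (any(tab$failed)) {
    warning(sum(tab$failed), " candidate model(s) failed to fit and were excluded",
            call. = FALSE)
  }
  ok <- tab[!tab$failed, setdiff(names(tab), "failed")]
  # round before ranking so exact ties (e.g. saturated fits) resolve by the
  # documented ladder rather than floating-point noise
  o <- order(-round(ok$adj_r2, 10), round(ok$aic, 8), ok$size, ok$subset)
  ok <- ok[o, ]
  ok$rank <- seq_len(nrow(ok))
  rownames(ok) <- NULL
  structure(list(ranking = ok,
                 best = strsplit(ok$subset[1], ",", fixed = TRUE)[[1]]),
            class = "agbgeo_selection")
}

#' @export
print.agbgeo_selection <- function(x, n = 5L, ...) {
  cat("Exhaustive 2-/3-metric OLS screening:", nrow(x$ranking), "candidates\n")
  cat("best subset:", paste(x$best, collapse = " + "), "\n")
  print(utils::head(x$ranking, n), digits = 4)
  invisible(x)
}
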