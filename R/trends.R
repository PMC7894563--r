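#' Linear trend with AR(1)-correlated errors
#'
#' Fits `y = a + b x` by generalised least squares where residuals at
#' times t1, t2 are correlated as `phi^|t1 - t2|`. The AR(1) coefficient
#' is estimated jointly with the regression by (restricted) maximum
#' likelihood via [nlme::gls()]; because the time axis enters the
#' correlation as a continuous covariate, missing years do not shorten
#' lags. With `phi` fixed at 0 the fit reduces exactly to ordinary least
#' squares. Two-sided p-values use the t distribution with n - 2 degrees
#' of freedom.
#'
#' @param x numeric predictor (typically calendar year; must be
#'   integer-valued for the AR(1) correlation structure).
#' @param y numeric response.
#' @param phi `NULL` to estimate the AR(1) coefficient, or a fixed value
#'   in (-1, 1) (0 gives OLS).
#' @return object of class `pm_trend`: list with `slope`, `slope_se`,
#'   `intercept`, `p_value`, `phi`, `n`.
#' @export
fit_gls_ar1 <- function(x, y, phi = NULL) {
  dat <- check_xy(x, y, min_n = 4)
  if (!is.null(phi)) {
    if (abs(phi) >= 1) stop("fixed phi must lie in (-1, 1)")
    return(gls_ar1_fixed(dat$xi, dat$yv, phi))
  }
  fit <- tryCatch(
    nlme::gls(yv ~ xi, data = dat,
              correlation = nlme::corAR1(form = ~ xi), method = "REML"),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate (e.g. exact-fit) inputs: profile the AR(1) coefficient
    # over a grid of prewhitened fits instead
    grid <- seq(-0.95, 0.95, by = 0.05)
    fits <- lapply(grid, function(p) gls_ar1_fixed(dat$xi, dat$yv, p))
    ll <- vapply(fits, function(f) f$logLik, numeric(1))
    best <- which.max(ll)
    out <- fits[[best]]
    out$phi <- grid[best]
    return(out)
  }
  tt <- summary(fit)$tTable
  phi_hat <- unname(coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  new_trend(unname(tt["xi", "Value"]), unname(tt["xi", "Std.Error"]),
            unname(tt["(Intercept)", "Value"]), phi_hat, nrow(dat))
}

# GLS under a known AR(1) coefficient: prewhiten with the Cholesky root of
# the correlation matrix phi^|t1 - t2| and refit by OLS. Reduces exactly
# to OLS at phi = 0.
gls_ar1_fixed <- function(x, y, phi) {
  n <- length(x)
  C <- phi^abs(outer(x, x, "-"))
  R <- chol(C)
  Xw <- backsolve(R, cbind(1, x), transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  fit <- lm(yw ~ Xw - 1)
  s <- suppressWarnings(summary(fit)$coefficients)
  out <- new_trend(unname(s[2, "Estimate"]), unname(s[2, "Std. Error"]),
                   unname(s[1, "Estimate"]), phi, n)
  rss <- sum(resid(fit)^2)
  sigma2 <- rss / (n - 2)
  out$logLik <- if (sigma2 > 0) {
    # REML log-likelihood up to additive constants shared across phi
    -0.5 * ((n - 2) * log(sigma2) + 2 * sum(log(diag(R))) +
              determinant(crossprod(Xw), logarithm = TRUE)$modulus[1] +
              rss / sigma2)
  } else Inf
  out
}

#' Ordinary least squares trend
#'
#' Equivalent to [fit_gls_ar1()] with `phi` fixed at 0.
#'
#' @inheritParams fit_gls_ar1
#' @return a `pm_trend` object with `phi = 0`.
#' @export
fit_ols <- function(x, y) {
  dat <- check_xy(x, y, min_n = 3)
  fit <- lm(yv ~ xi, data = dat)
  s <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(dat) >= 3) unname(s["xi", "Std. Error"]) else NA_real_
  new_trend(unname(s["xi", "Estimate"]), se,
            unname(s["(Intercept)", "Estimate"]), 0, nrow(dat))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with a 95% interval from the Fisher
#' z-transform (`atanh(r) +/- 1.96 / sqrt(n - 3)`, back-transformed) and a
#' two-sided p-value from the t distribution with n - 2 df.
#'
#' @param x,y numeric vectors of equal length, n >= 3 (n >= 4 for a
#'   finite-width interval; at n = 3 the Fisher interval is (-1, 1)).
#' @return object of class `pm_correlation`: list with `r`, `ci_low`,
#'   `ci_high`, `n`, `p_value`.
#' @export
pearson_ci <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in x or y: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  half <- if (n > 3) 1.96 / sqrt(n - 3) else Inf
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  structure(list(r = r, ci_low = tanh(z - half), ci_high = tanh(z + half),
                 n = n, p_value = 2 * pt(-abs(tstat), df = n - 2)),
            class = "pm_correlation")
}

check_xy <- function(x, y, min_n) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad) > 0)
    stop(sprintf("non-finite values at row(s): %s",
                 paste(bad, collapse = ", ")))
  if (length(x) < min_n)
    stop(sprintf("need at least %d complete (x, y) pairs", min_n))
  if (length(unique(x)) < 2) stop("constant x: slope undefined")
  data.frame(xi = x, yv = y)
}

new_trend <- function(slope, se, intercept, phi, n) {
  p <- if (is.finite(se) && se > 0)
    2 * pt(-abs(slope / se), df = n - 2) else NA_real_
  structure(list(slope = slope, slope_se = se, intercept = intercept,
                 p_value = p, phi = phi, n = n),
            class = "pm_trend")
}

#' @export
print.pm_trend <- function(x, ...) {
  cat(sprintf("Trend: slope = %.4g +/- %.4g, p = %.4g, phi = %.3g, n = %d\n",
              x$slope, x$slope_se, x$p_value, x$phi, x$n))
  invisible(x)
}

#' @export
print.pm_correlation <- function(x, ...) {
  cat(sprintf("r = %.3f (95%% CI %.3f, %.3f), n = %d, p = %.3g\n",
              x$r, x$ci_low, x$ci_high, x$n, x$p_value))
  invisible(x)
}
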