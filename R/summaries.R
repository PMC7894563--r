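#' Posterior coefficient table
#'
#' Posterior mean, 95% credible interval (2.5% and 97.5% draw quantiles)
#' and a significance flag for each parameter. Significance is the
#' interval-excludes-zero rule; no p-values are attached to Bayesian
#' fits.
#'
#' @param posterior a `pm_posterior` object (or a plain draws matrix with
#'   named columns).
#' @param parameters optional subset of parameter names.
#' @return data.frame with columns `parameter`, `mean`, `lower`, `upper`,
#'   `significant`.
#' @export
summarize_posterior <- function(posterior, parameters = NULL) {
  draws <- if (inherits(posterior, "pm_posterior")) {
    as.matrix(posterior$draws)
  } else as.matrix(posterior)
  if (nrow(draws) < 1) stop("empty posterior")
  if (nrow(draws) < 100)
    warning("fewer than 100 retained draws; interval estimates are crude")
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, colnames(draws))
    if (length(missing) > 0)
      stop(sprintf("unknown parameter(s): %s",
                   paste(missing, collapse = ", ")))
    draws <- draws[, parameters, drop = FALSE]
  }
  qs <- t(apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  out <- data.frame(parameter = colnames(draws),
                    mean = colMeans(draws),
                    lower = qs[, 1], upper = qs[, 2])
  out$significant <- out$lower > 0 | out$upper < 0
  rownames(out) <- NULL
  out
}

#' Vertex of the quadratic selection surface
#'
#' The lay date (relative to the annual mean) at which expected breeding
#' success peaks, computed per posterior draw as `-b / (2a)` with `b` the
#' linear and `a` the quadratic relative-lay-date coefficient, then
#' summarised by the posterior mean and 95% quantile interval. Negative
#' values are days before the annual mean. Summarising the ratio per draw
#' is not the same as taking the ratio of the summaries; the posterior
#' mean of the ratio is the reported estimate.
#'
#' @param posterior a `pm_posterior` from a fit including the quadratic
#'   term.
#' @return object of class `pm_vertex`: list with `estimate`, `ci_low`,
#'   `ci_high`, `draws`, `n_excluded` (draws with a zero quadratic
#'   coefficient, dropped with a warning if more than 5%).
#' @export
vertex <- function(posterior) {
  draws <- as.matrix(posterior$draws)
  need <- c("rel_date", "rel_date_sq")
  if (!all(need %in% colnames(draws)))
    stop("posterior lacks the quadratic relative-lay-date term")
  b <- draws[, "rel_date"]
  a <- draws[, "rel_date_sq"]
  keep <- a != 0
  n_excluded <- sum(!keep)
  if (n_excluded > 0.05 * length(a))
    warning(sprintf("%d of %d draws have a zero quadratic coefficient",
                    n_excluded, length(a)))
  v <- -b[keep] / (2 * a[keep])
  structure(list(estimate = mean(v),
                 ci_low = unname(quantile(v, 0.025)),
                 ci_high = unname(quantile(v, 0.975)),
                 draws = v, n_excluded = n_excluded),
            class = "pm_vertex")
}

#' @export
print.pm_vertex <- function(x, ...) {
  cat(sprintf("Vertex: %.2f days relative to annual mean (95%% CI %.2f, %.2f)\n",
              x$estimate, x$ci_low, x$ci_high))
  invisible(x)
}

#' Among-year variance of the within-year selection slope
#'
#' Quantile summary of the posterior of the year-level slope variance,
#' used to assess whether the strength of selection on relative lay date
#' varies among years.
#'
#' @param posterior a `pm_posterior` object.
#' @return list with `estimate`, `ci_low`, `ci_high`, `draws`.
#' @export
slope_variance <- function(posterior) {
  draws <- as.matrix(posterior$draws)
  col <- if ("var_slope" %in% colnames(draws)) "var_slope" else "var_W_Sh"
  if (!col %in% colnames(draws)) stop("posterior lacks a slope variance")
  v <- draws[, col]
  list(estimate = mean(v), ci_low = unname(quantile(v, 0.025)),
       ci_high = unname(quantile(v, 0.975)), draws = v)
}

#' Rate of advance of the optimum lay date
#'
#' Environmental sensitivity of the optimum: with the optimum in
#' environmental state E written as `O(E) = xbar(E) + v(E)` where
#' `v(E) = -(beta_W + beta_int * E) / (2 gamma)` is the within-year
#' vertex, the rate of change is
#' `B = dO/dE = d xbar/dE - beta_int / (2 gamma)`.
#' The first term is the (fixed) trend of annual mean timing on E; the
#' second combines the interaction and quadratic coefficients per
#' posterior draw. The credible interval combines the draw quantiles with
#' the timing-trend slope's sampling SE in quadrature.
#'
#' @param posterior a `pm_posterior` from the matching variant (`year`
#'   for covariate "year", `sst_current` for covariate "sst").
#' @param timing_trend a `pm_trend` of annual mean lay date on the
#'   covariate.
#' @param covariate "year" (days/year) or "sst" (days/deg C).
#' @return object of class `pm_sensitivity`: list with `B`, `ci_low`,
#'   `ci_high`, `decomposition` (timing-trend and relative-optimum
#'   components), `covariate`.
#' @export
optimum_sensitivity <- function(posterior, timing_trend,
                                covariate = c("year", "sst")) {
  covariate <- match.arg(covariate)
  stopifnot(inherits(timing_trend, "pm_trend"))
  draws <- as.matrix(posterior$draws)
  int_col <- if (covariate == "year") "rel_date:year_c" else "rel_date:sst"
  if (!int_col %in% colnames(draws))
    stop(sprintf(
      "posterior lacks '%s'; fit the '%s' variant for covariate '%s'",
      int_col, if (covariate == "year") "year" else "sst_current", covariate))
  if (!"rel_date_sq" %in% colnames(draws))
    stop("posterior lacks the quadratic relative-lay-date term")
  bint <- draws[, int_col]
  a <- draws[, "rel_date_sq"]
  keep <- a != 0
  shift <- -bint[keep] / (2 * a[keep])
  Bdraws <- timing_trend$slope + shift
  est <- timing_trend$slope + mean(shift)
  q <- quantile(Bdraws, c(0.025, 0.975), names = FALSE)
  se <- timing_trend$slope_se
  widen <- if (is.finite(se)) 1.96 * se else 0
  ci_low <- est - sqrt((est - q[1])^2 + widen^2)
  ci_high <- est + sqrt((q[2] - est)^2 + widen^2)
  structure(list(B = est, ci_low = ci_low, ci_high = ci_high,
                 decomposition = list(timing_trend = timing_trend$slope,
                                      optimum_shift = mean(shift)),
                 covariate = covariate),
            class = "pm_sensitivity")
}

#' @export
print.pm_sensitivity <- function(x, ...) {
  unit <- if (x$covariate == "year") "days/year" else "days/degC"
  cat(sprintf("B = %.3f %s (95%% CI %.3f, %.3f)\n", x$B, unit,
              x$ci_low, x$ci_high))
  invisible(x)
}
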