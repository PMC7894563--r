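#' Offset logit transform for proportions
#'
#' `log((p + 0.01) / (1 - p + 0.01))`: a logit with 0.01 added to both
#' numerator and denominator so that proportions of exactly 0 and 1 map
#' to finite values (-log(101) and +log(101)) instead of -Inf / +Inf.
#' Strictly increasing and antisymmetric about p = 0.5.
#'
#' @param p proportion(s) in [0, 1].
#' @return offset-logit value(s).
#' @seealso [inv_logit_offset()]
#' @export
logit_offset <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  log((p + 0.01) / (1 - p + 0.01))
}

#' Inverse of the offset logit
#'
#' Solves `g = log((p + 0.01) / (1 - p + 0.01))` for p and clips the
#' result to [0, 1] (values of |g| beyond log(101) fall outside the
#' representable proportion range). Round-trips with [logit_offset()] to
#' machine precision on (0, 1).
#'
#' @param g offset-logit value(s).
#' @return proportion(s) in [0, 1].
#' @export
inv_logit_offset <- function(g) {
  eg <- exp(g)
  p <- (1.01 * eg - 0.01) / (1 + eg)
  pmin(pmax(p, 0), 1)
}

#' Fit the seasonal diet-shift model
#'
#' Gaussian random-regression model of the offset-logit proportion of 1+
#' group sandeels among sandeels in regurgitate samples. The within-year
#' axis is the sample's collection date centred on the annual mean
#' collection date; year-level random intercepts and relative-date slopes
#' carry an unstructured 2x2 covariance, and the residual variance is
#' estimated under an inverse-Wishart (scaled inverse-chi-squared) prior.
#'
#' Variants:
#' \describe{
#'   \item{sandeel_core}{intercept, grand-mean-centred annual mean sample
#'     date, relative sample date}
#'   \item{sandeel_year}{intercept, centred year, relative sample date,
#'     and the year x relative-date interaction}
#' }
#'
#' Years contributing a single sample have a relative date of exactly 0,
#' so they inform intercepts only; this is reported with a message, not
#' an error.
#'
#' @param diet data.frame with columns `year`, `sample_date`,
#'   `prop_oneplus` (only sandeel-containing samples).
#' @param variant fixed-effect roster, see Details.
#' @param mcmc a [mcmc_settings()] object.
#' @param prior a [prior_spec()] object.
#' @return a `pm_posterior`; variance components are labelled
#'   `var_intercept`, `cov_int_slope`, `var_slope`, and the residual
#'   variance `sigma2_resid`.
#' @export
fit_diet_model <- function(diet, variant = c("sandeel_core", "sandeel_year"),
                           mcmc = mcmc_settings(), prior = prior_spec()) {
  variant <- match.arg(variant)
  req <- c("year", "sample_date", "prop_oneplus")
  miss <- setdiff(req, names(diet))
  if (length(miss) > 0)
    stop(sprintf("diet table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(diet$prop_oneplus < 0 | diet$prop_oneplus > 1))
    stop("prop_oneplus must lie in [0, 1]")
  years <- sort(unique(diet$year))
  if (length(years) < 3) stop("need at least 3 years of diet samples")
  counts <- table(diet$year)
  if (any(counts == 1))
    message(sprintf(
      "%d year(s) have a single sample and inform intercepts only",
      sum(counts == 1)))

  yi <- match(diet$year, years)
  dbar <- as.numeric(tapply(diet$sample_date, diet$year, mean))
  rel <- diet$sample_date - dbar[yi]
  y <- logit_offset(diet$prop_oneplus)
  yc <- years - mean(years)

  if (variant == "sandeel_core") {
    X <- cbind("(Intercept)" = 1, mean_sample_date = (dbar - mean(dbar))[yi],
               rel_date = rel)
  } else {
    X <- cbind("(Intercept)" = 1, year_c = yc[yi], rel_date = rel,
               "rel_date:year_c" = rel * yc[yi])
  }
  run_gibbs(y = y, size = rep(0, length(y)), fam = rep(0L, length(y)),
            X = X, year_index = yi, years = years,
            Z = cbind(intercept = 1, rel_date = rel),
            sigma_labels = c("var_intercept", "cov_int_slope", "var_slope"),
            mcmc = mcmc, prior = prior, family = "gaussian",
            variant = variant,
            centring = list(mean_sample_date = mean(dbar),
                            year = mean(years)))
}
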