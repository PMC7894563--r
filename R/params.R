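#' Parameters of the synthetic colony study generator
#'
#' Bundles every generative parameter used by the simulator. Defaults
#' reproduce the structure of a three-decade seabird colony study: 30
#' breeding seasons from 1987 with two missing years, 35--266 monitored
#' nests per year, late-winter sea surface temperature (SST) warming on
#' top of AR(1) noise, advancing mean lay dates that respond to SST,
#' latent-logit binomial fledging out of a maximum brood of four with
#' correlated year-level random intercepts and relative-lay-date slopes,
#' and regurgitate diet samples whose 1+ group sandeel proportion declines
#' within each season on the offset-logit scale.
#'
#' Year-level random effects for breeding success and diet are drawn
#' jointly from a 4x4 covariance over (B_Sh, B_Sa, W_Sh, W_Sa): year
#' intercept deviations (B) and within-year slope deviations (W) for the
#' shag fitness trait (Sh) and the sandeel diet trait (Sa). When
#' `cross_cov` is `NULL` it is assembled block-diagonally from the
#' marginal variances and `rho_int_slope`, with zero cross-trait
#' covariance.
#'
#' @param n_years number of breeding seasons (>= 3).
#' @param start_year first calendar year.
#' @param nests_per_year integer range (min, max); annual counts drawn
#'   uniformly.
#' @param gap_years calendar years dropped after generation (no data).
#' @param sst_mean,sst_trend,sst_ar_phi,sst_sd SST process: mean (deg C),
#'   linear trend (deg C/year), AR(1) coefficient in (-1, 1), innovation
#'   SD (deg C).
#' @param laydate_intercept mean lay date (ordinal day, Jan 1 = 0) at the
#'   study midpoint.
#' @param laydate_trend days/year.
#' @param laydate_sst_slope days per deg C of SST anomaly.
#' @param laydate_year_sd SD of annual-mean lay-date noise (days).
#' @param laydate_within_sd within-year SD of nest lay dates (days).
#' @param mu latent logit intercept of fledging success.
#' @param beta_B logit units per day of (centred) annual mean lay date.
#' @param beta_W logit units per day of relative lay date.
#' @param gamma logit units per day^2 (quadratic in relative lay date).
#' @param beta_W_year,beta_W_sst interactions of relative lay date with
#'   centred year and centred SST (logit/day/year, logit/day/deg C).
#' @param sigma2_int among-year variance of latent intercepts (logit^2).
#' @param sigma2_slope among-year variance of relative-date slopes.
#' @param rho_int_slope correlation of year intercept and slope effects.
#' @param resid_sd latent residual SD (fixed at 1 to mirror the binomial
#'   fit's fixed residual variance).
#' @param diet_mu offset-logit intercept of the 1+ group proportion at the
#'   annual mean sample date.
#' @param diet_within_slope within-year slope (logit/day).
#' @param diet_sigma2_int,diet_sigma2_slope among-year variances of diet
#'   intercepts and within-year slopes.
#' @param diet_resid_sd residual SD of the offset-logit proportion.
#' @param diet_date_offset mean collection date minus mean lay date (days).
#' @param diet_date_sd SD of collection dates about their mean (days).
#' @param samples_per_year integer range of regurgitate samples per year.
#' @param cross_cov optional 4x4 symmetric positive semi-definite matrix
#'   over (B_Sh, B_Sa, W_Sh, W_Sa); overrides the marginal variance and
#'   correlation arguments when supplied.
#'
#' @return an object of class `pm_params` (a named list).
#' @export
simulation_params <- function(n_years = 30,
                              start_year = 1987,
                              nests_per_year = c(35, 266),
                              gap_years = c(1993, 2003),
                              sst_mean = 5.94,
                              sst_trend = 0.02,
                              sst_ar_phi = 0.27,
                              sst_sd = 0.35,
                              laydate_intercept = 127,
                              laydate_trend = -0.94,
                              laydate_sst_slope = -6.30,
                              laydate_year_sd = 6,
                              laydate_within_sd = 12,
                              mu = -0.5,
                              beta_B = -0.035,
                              beta_W = -0.026,
                              gamma = -0.0007,
                              beta_W_year = 0,
                              beta_W_sst = 0,
                              sigma2_int = 0.3,
                              sigma2_slope = 1e-4,
                              rho_int_slope = 0,
                              resid_sd = 1,
                              diet_mu = 1.4,
                              diet_within_slope = -0.095,
                              diet_sigma2_int = 6.46,
                              diet_sigma2_slope = 0.015,
                              diet_resid_sd = 1.5,
                              diet_date_offset = 30,
                              diet_date_sd = 20,
                              samples_per_year = c(4, 69),
                              cross_cov = NULL) {
  p <- as.list(environment())
  if (p$n_years < 3) stop("n_years must be >= 3")
  if (length(p$nests_per_year) != 2 || p$nests_per_year[1] < 1)
    stop("nests_per_year must be a range (min, max) with min >= 1")
  if (length(p$samples_per_year) != 2 || p$samples_per_year[1] < 1)
    stop("samples_per_year must be a range (min, max) with min >= 1")
  if (abs(p$sst_ar_phi) >= 1)
    stop("sst_ar_phi must lie strictly inside (-1, 1) for stationarity")
  vars <- c("sigma2_int", "sigma2_slope", "diet_sigma2_int",
            "diet_sigma2_slope")
  for (v in vars) if (p[[v]] < 0) stop(sprintf("%s must be >= 0", v))
  if (abs(p$rho_int_slope) > 1) stop("|rho_int_slope| must be <= 1")
  if (is.null(cross_cov)) {
    cc <- diag(c(p$sigma2_int, p$diet_sigma2_int,
                 p$sigma2_slope, p$diet_sigma2_slope))
    cov_is <- p$rho_int_slope * sqrt(p$sigma2_int * p$sigma2_slope)
    cc[1, 3] <- cc[3, 1] <- cov_is
    p$cross_cov <- cc
  } else {
    cc <- as.matrix(cross_cov)
    if (!isTRUE(all.equal(cc, t(cc), tolerance = 1e-8)))
      stop("cross_cov must be symmetric")
    if (min(eigen(cc, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("cross_cov must be positive semi-definite")
    p$cross_cov <- cc
  }
  dimnames(p$cross_cov) <- list(c("B_Sh", "B_Sa", "W_Sh", "W_Sa"),
                                c("B_Sh", "B_Sa", "W_Sh", "W_Sa"))
  structure(p, class = "pm_params")
}

#' @export
print.pm_params <- function(x, ...) {
  cat("Synthetic study parameters (pm_params)\n")
  cat(sprintf("  %d years from %d (%d gap year%s), %d-%d nests/year\n",
              x$n_years, x$start_year, length(x$gap_years),
              if (length(x$gap_years) == 1) "" else "s",
              x$nests_per_year[1], x$nests_per_year[2]))
  cat(sprintf("  fitness: mu=%.3g beta_B=%.3g beta_W=%.3g gamma=%.3g\n",
              x$mu, x$beta_B, x$beta_W, x$gamma))
  cat(sprintf("  diet: mu=%.3g slope=%.3g\n", x$diet_mu, x$diet_within_slope))
  invisible(x)
}
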