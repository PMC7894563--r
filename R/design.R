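#' Build the model design for a breeding-success fit
#'
#' Decomposes lay date into its annual mean (between-year axis) and each
#' nest's deviation from that mean (within-year axis). The relative
#' column is centred within year exactly; annual mean lay date, year and
#' SST are grand-mean centred; population size enters as a centred
#' natural log. The response is (successes, failures) = (n_fledged,
#' 4 - n_fledged).
#'
#' Variants add fixed effects to the core roster (intercept, mean lay
#' date, relative lay date, relative lay date squared):
#' \describe{
#'   \item{core}{no extras}
#'   \item{core_popsize}{log population size}
#'   \item{year}{centred year and its interaction with relative lay date}
#'   \item{sst_current}{centred year, centred SST, SST x relative lay date}
#'   \item{sst_previous}{as sst_current using previous-year SST}
#' }
#'
#' @param breeding data.frame with columns `year`, `nest_id`, `lay_date`,
#'   `n_fledged` and optionally `attempt` (rows with attempt > 1 are
#'   dropped with a message; replacement clutches are excluded from the
#'   core analyses).
#' @param context optional data.frame with one row per year (`year`,
#'   `sst`, `sst_prev`, `population_size`); required for variants that use
#'   those covariates.
#' @param variant fixed-effect roster, see Details.
#' @param include_quadratic include the (relative lay date)^2 column.
#' @return object of class `pm_design`.
#' @export
build_design <- function(breeding, context = NULL,
                         variant = c("core", "core_popsize", "year",
                                     "sst_current", "sst_previous"),
                         include_quadratic = TRUE) {
  variant <- match.arg(variant)
  req <- c("year", "nest_id", "lay_date", "n_fledged")
  miss <- setdiff(req, names(breeding))
  if (length(miss) > 0)
    stop(sprintf("breeding table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if ("attempt" %in% names(breeding)) {
    drop <- breeding$attempt > 1
    if (any(drop)) {
      message(sprintf("dropping %d replacement-clutch row(s) (attempt > 1)",
                      sum(drop)))
      breeding <- breeding[!drop, , drop = FALSE]
    }
  }
  bad <- which(!is.finite(breeding$n_fledged) |
                 breeding$n_fledged < 0 | breeding$n_fledged > 4 |
                 breeding$n_fledged != round(breeding$n_fledged))
  if (length(bad) > 0)
    stop(sprintf("n_fledged outside 0..4 at row(s): %s",
                 paste(bad, collapse = ", ")))

  years <- sort(unique(breeding$year))
  if (variant != "core" && is.null(context))
    stop(sprintf("variant '%s' needs a year-context table", variant))
  if (!is.null(context)) {
    missing_years <- setdiff(years, context$year)
    if (length(missing_years) > 0)
      stop(sprintf("context table missing year(s): %s",
                   paste(missing_years, collapse = ", ")))
  }

  yi <- match(breeding$year, years)
  xbar <- as.numeric(tapply(breeding$lay_date, breeding$year, mean))
  rel <- breeding$lay_date - xbar[yi]
  xbar_c <- xbar - mean(xbar)
  yc <- years - mean(years)

  X <- cbind("(Intercept)" = 1, mean_lay_date = xbar_c[yi], rel_date = rel)
  if (include_quadratic) X <- cbind(X, rel_date_sq = rel^2)
  if (variant == "core_popsize") {
    lp <- log(context$population_size[match(years, context$year)])
    X <- cbind(X, log_popsize = (lp - mean(lp))[yi])
  } else if (variant == "year") {
    X <- cbind(X, year_c = yc[yi], "rel_date:year_c" = rel * yc[yi])
  } else if (variant %in% c("sst_current", "sst_previous")) {
    scol <- if (variant == "sst_current") "sst" else "sst_prev"
    s <- context[[scol]][match(years, context$year)]
    sc <- s - mean(s)
    X <- cbind(X, year_c = yc[yi], sst = sc[yi],
               "rel_date:sst" = rel * sc[yi])
  }

  structure(list(successes = as.integer(breeding$n_fledged),
                 failures = as.integer(4 - breeding$n_fledged),
                 size = 4L, X = X, year_index = yi, years = years,
                 Z = cbind(intercept = 1, rel_date = rel),
                 family = "binomial", variant = variant,
                 centring = list(mean_lay_date = mean(xbar),
                                 year = mean(years)),
                 n = nrow(breeding)),
            class = "pm_design")
}

#' @export
print.pm_design <- function(x, ...) {
  cat(sprintf("pm_design (%s, %s): %d obs, %d years, %d fixed effects\n",
              x$family, x$variant, x$n, length(x$years), ncol(x$X)))
  invisible(x)
}
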