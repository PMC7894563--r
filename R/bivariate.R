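#' Joint model of breeding success and diet composition
#'
#' Fits nest-level fledging success (binomial logit, latent residual
#' fixed at 1) and the offset-logit 1+ group sandeel proportion
#' (Gaussian, residual estimated) as a bivariate response sharing
#' year-level random effects. Each year carries a 4-vector of effects
#' (B_Sh, B_Sa, W_Sh, W_Sa) -- intercept (B) and within-year slope (W)
#' deviations for the shag fitness trait (Sh) and the sandeel diet trait
#' (Sa) -- with an unstructured 4x4 covariance sampled jointly by
#' inverse-Wishart updates, so every draw is symmetric positive
#' definite. The match-mismatch predictions are positive covariances
#' sigma(B_Sa, B_Sh) and sigma(W_Sa, W_Sh).
#'
#' Within-year timing for *both* traits is centred on the annual mean
#' lay date. Fixed effects follow the univariate rosters: intercept,
#' centred annual mean lay date, relative lay date and its square for
#' breeding success; intercept, centred annual mean lay date and
#' relative (collection) date for diet -- the quadratic applies to the
#' fitness trait only.
#'
#' Years present in only one table are retained and inform their own
#' trait's parameters, linked to the other trait through the covariance.
#' Diet-only years take their annual mean lay date from `context` when
#' available, otherwise from that year's mean sample date (reported with
#' a message).
#'
#' @param breeding data.frame of nest records (`year`, `nest_id`,
#'   `lay_date`, `n_fledged`).
#' @param diet data.frame of diet samples (`year`, `sample_date`,
#'   `prop_oneplus`).
#' @param context optional year table with `year` and `mean_lay_date`
#'   used for diet-only years.
#' @param mcmc chain settings; defaults to the long bivariate profile
#'   (400,000 iterations, 40,000 burn-in, thin 10).
#' @param prior a [prior_spec()] object.
#' @return a `pm_posterior` (additional class `pm_bivariate`) whose
#'   covariance draws are labelled `var_B_Sh`, `cov_B_Sh_B_Sa`, ...,
#'   `var_W_Sa`.
#' @export
fit_bivariate <- function(breeding, diet, context = NULL,
                          mcmc = mcmc_settings(n_iterations = 400000,
                                               burn_in = 40000, thin = 10),
                          prior = prior_spec()) {
  overlap <- intersect(unique(breeding$year), unique(diet$year))
  if (length(overlap) < 3)
    stop("need at least 3 overlapping years between breeding and diet")
  bad <- which(breeding$n_fledged < 0 | breeding$n_fledged > 4)
  if (length(bad) > 0)
    stop(sprintf("n_fledged outside 0..4 at row(s): %s",
                 paste(bad, collapse = ", ")))
  if (any(diet$prop_oneplus < 0 | diet$prop_oneplus > 1))
    stop("prop_oneplus must lie in [0, 1]")

  years <- sort(union(unique(breeding$year), unique(diet$year)))
  xbar <- rep(NA_real_, length(years))
  names(xbar) <- years
  bm <- tapply(breeding$lay_date, breeding$year, mean)
  xbar[names(bm)] <- bm
  need <- is.na(xbar)
  if (any(need)) {
    if (!is.null(context) && "mean_lay_date" %in% names(context)) {
      idx <- match(as.integer(names(xbar)[need]), context$year)
      xbar[need] <- context$mean_lay_date[idx]
      need <- is.na(xbar)
    }
    if (any(need)) {
      dm <- tapply(diet$sample_date, diet$year, mean)
      xbar[need] <- dm[names(xbar)[need]]
      message(sprintf(
        "%d diet-only year(s) use their mean sample date as the timing centre",
        sum(need)))
    }
  }
  xbar_c <- xbar - mean(xbar)

  yi_b <- match(breeding$year, years)
  rel_b <- breeding$lay_date - xbar[yi_b]
  yi_d <- match(diet$year, years)
  rel_d <- diet$sample_date - xbar[yi_d]

  n_b <- nrow(breeding); n_d <- nrow(diet)
  # stacked fixed-effect design, block structure by trait
  X <- matrix(0, n_b + n_d, 7,
              dimnames = list(NULL, c("sh:(Intercept)", "sh:mean_lay_date",
                                      "sh:rel_date", "sh:rel_date_sq",
                                      "sa:(Intercept)", "sa:mean_lay_date",
                                      "sa:rel_date")))
  X[seq_len(n_b), 1] <- 1
  X[seq_len(n_b), 2] <- xbar_c[yi_b]
  X[seq_len(n_b), 3] <- rel_b
  X[seq_len(n_b), 4] <- rel_b^2
  X[n_b + seq_len(n_d), 5] <- 1
  X[n_b + seq_len(n_d), 6] <- xbar_c[yi_d]
  X[n_b + seq_len(n_d), 7] <- rel_d

  # year-effect loadings, order (B_Sh, B_Sa, W_Sh, W_Sa)
  Z <- matrix(0, n_b + n_d, 4,
              dimnames = list(NULL, c("B_Sh", "B_Sa", "W_Sh", "W_Sa")))
  Z[seq_len(n_b), 1] <- 1
  Z[seq_len(n_b), 3] <- rel_b
  Z[n_b + seq_len(n_d), 2] <- 1
  Z[n_b + seq_len(n_d), 4] <- rel_d

  labels <- c("var_B_Sh", "cov_B_Sh_B_Sa", "cov_B_Sh_W_Sh", "cov_B_Sh_W_Sa",
              "var_B_Sa", "cov_B_Sa_W_Sh", "cov_B_Sa_W_Sa",
              "var_W_Sh", "cov_W_Sh_W_Sa", "var_W_Sa")
  out <- run_gibbs(y = c(breeding$n_fledged, logit_offset(diet$prop_oneplus)),
                   size = c(rep(4, n_b), rep(0, n_d)),
                   fam = c(rep(1L, n_b), rep(0L, n_d)),
                   X = X, year_index = c(yi_b, yi_d), years = years,
                   Z = Z, sigma_labels = labels, mcmc = mcmc, prior = prior,
                   family = "bivariate", variant = "bivariate_core",
                   centring = list(mean_lay_date = mean(xbar),
                                   year = mean(years)))
  class(out) <- c("pm_bivariate", class(out))
  out
}

#' Summarise the year-level covariance matrix
#'
#' Posterior mean, 95% credible interval and a sign flag (interval
#' excludes zero) for every entry of the 4x4 year-level covariance, with
#' the corresponding correlations computed per draw for off-diagonal
#' entries (Cauchy-Schwarz bounds them to [-1, 1] draw by draw).
#'
#' @param posterior a [fit_bivariate()] posterior.
#' @return data.frame with one row per unique covariance entry: `entry`,
#'   `row`, `col`, `mean`, `lower`, `upper`, `significant`,
#'   `correlation`.
#' @export
covariance_summary <- function(posterior) {
  draws <- as.matrix(posterior$draws)
  traits <- c("B_Sh", "B_Sa", "W_Sh", "W_Sa")
  vcols <- paste0("var_", traits)
  if (!all(vcols %in% colnames(draws)))
    stop("posterior does not carry a 4x4 year-level covariance")
  if (nrow(draws) < 100)
    warning("fewer than 100 retained draws; interval estimates are crude")
  rows <- list()
  for (a in 1:4) {
    for (b in a:4) {
      col <- if (a == b) vcols[a] else {
        cands <- c(sprintf("cov_%s_%s", traits[a], traits[b]),
                   sprintf("cov_%s_%s", traits[b], traits[a]))
        cands[cands %in% colnames(draws)][1]
      }
      d <- draws[, col]
      corr <- if (a == b) NA_real_ else {
        mean(d / sqrt(draws[, vcols[a]] * draws[, vcols[b]]))
      }
      q <- quantile(d, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        entry = col, row = traits[a], col = traits[b], mean = mean(d),
        lower = q[1], upper = q[2],
        significant = q[1] > 0 | q[2] < 0, correlation = corr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
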