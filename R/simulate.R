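#' Simulate the late-winter SST series
#'
#' Generates one mean February/March sea surface temperature per simulated
#' year as `sst_mean + sst_trend * (year - midpoint) + AR(1) noise`, with
#' the lag-1 value for the first year drawn from the stationary
#' distribution (an extra pre-study year is simulated so `sst_prev` is
#' defined throughout).
#'
#' @param params a [simulation_params()] object.
#' @param seed integer seed; identical seeds give identical series.
#' @return data.frame with columns `year`, `sst`, `sst_prev`.
#' @export
simulate_sst <- function(params, seed = 1) {
  stopifnot(inherits(params, "pm_params"))
  if (abs(params$sst_ar_phi) >= 1)
    stop("sst_ar_phi must lie strictly inside (-1, 1) for stationarity")
  years <- seq(params$start_year, length.out = params$n_years)
  all_years <- c(years[1] - 1L, years)     # extra year for the lag column
  yc <- all_years - mean(years)
  phi <- params$sst_ar_phi
  withr::with_seed(seed, {
    n <- length(all_years)
    e <- numeric(n)
    stat_sd <- if (params$sst_sd > 0) params$sst_sd / sqrt(1 - phi^2) else 0
    e[1] <- rnorm(1, 0, stat_sd)
    if (n > 1) {
      innov <- rnorm(n - 1, 0, params$sst_sd)
      for (t in 2:n) e[t] <- phi * e[t - 1] + innov[t - 1]
    }
    sst <- params$sst_mean + params$sst_trend * yc + e
  })
  data.frame(year = years, sst = sst[-1],
             sst_prev = sst[-length(sst)])
}

#' Simulate nest-level lay dates
#'
#' Annual mean lay date follows a linear year trend plus a response to the
#' SST anomaly plus annual noise; nest lay dates scatter around the annual
#' mean with a Gaussian within-year spread and are rounded to integer
#' ordinal days. Gap years are dropped after generation so that year
#' remains a continuous covariate.
#'
#' @param params a [simulation_params()] object.
#' @param sst data.frame from [simulate_sst()] covering all simulated
#'   years.
#' @param seed integer seed.
#' @return data.frame with columns `year`, `nest_id`, `lay_date`.
#' @export
simulate_phenology <- function(params, sst, seed = 1) {
  stopifnot(inherits(params, "pm_params"))
  years <- seq(params$start_year, length.out = params$n_years)
  if (!all(years %in% sst$year))
    stop("SST series does not cover all simulated years")
  if (length(years) == 0) stop("empty year range")
  yc <- years - mean(years)
  sst_y <- sst$sst[match(years, sst$year)]
  withr::with_seed(seed, {
    mean_ld <- params$laydate_intercept + params$laydate_trend * yc +
      params$laydate_sst_slope * (sst_y - mean(sst_y)) +
      rnorm(length(years), 0, params$laydate_year_sd)
    rng <- params$nests_per_year
    n_nests <- rng[1] + sample.int(rng[2] - rng[1] + 1L, length(years),
                                   replace = TRUE) - 1L
    out <- do.call(rbind, lapply(seq_along(years), function(i) {
      ld <- round(mean_ld[i] + rnorm(n_nests[i], 0, params$laydate_within_sd))
      data.frame(year = years[i],
                 nest_id = sprintf("Y%d_N%03d", years[i], seq_len(n_nests[i])),
                 lay_date = as.integer(ld))
    }))
  })
  out[!(out$year %in% params$gap_years), , drop = FALSE]
}

#' Draw the joint year-level random effects
#'
#' One draw per year from the 4x4 covariance over (B_Sh, B_Sa, W_Sh,
#' W_Sa): breeding-success intercept and slope deviations jointly with the
#' diet intercept and slope deviations. [simulate_breeding()] and
#' [simulate_diet()] call this internally with the seed they are given, so
#' passing the same seed to both yields a single coherent joint draw; it
#' is exported so recovery tests can condition on the realisation.
#'
#' @param params a [simulation_params()] object.
#' @param years vector of calendar years to draw effects for.
#' @param seed integer seed.
#' @return matrix with one row per year, columns B_Sh, B_Sa, W_Sh, W_Sa.
#' @export
draw_year_effects <- function(params, years, seed = 1) {
  stopifnot(inherits(params, "pm_params"))
  cc <- params$cross_cov
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("cross_cov is not positive semi-definite")
  withr::with_seed(seed, {
    eff <- MASS::mvrnorm(length(years), mu = rep(0, 4), Sigma = cc)
  })
  eff <- matrix(eff, ncol = 4)
  rownames(eff) <- years
  colnames(eff) <- c("B_Sh", "B_Sa", "W_Sh", "W_Sa")
  eff
}

#' Simulate nest-level fledging success
#'
#' Each nest fledges `n_fledged ~ Binomial(4, logistic(eta))` chicks,
#' where the latent logit is
#' `mu + u_i + beta_B * xbar_c + (beta_W + w_i + beta_W_year * year_c +
#' beta_W_sst * sst_c) * rel + gamma * rel^2 + e`,
#' with `xbar_c` the centred annual mean lay date, `rel` the within-year
#' centred lay date, `(u_i, w_i)` the year's B_Sh / W_Sh random effects
#' and `e ~ N(0, resid_sd^2)` the latent residual (SD 1 by default,
#' mirroring the fixed residual variance of the binomial fit).
#'
#' @param phenology data.frame from [simulate_phenology()].
#' @param params a [simulation_params()] object.
#' @param seed integer seed (shared with [simulate_diet()] for a coherent
#'   joint draw of the year effects).
#' @param year_effects optional matrix from [draw_year_effects()].
#' @param sst optional SST series; required when `beta_W_sst != 0`.
#' @return data.frame with columns `year`, `nest_id`, `lay_date`,
#'   `n_fledged`.
#' @export
simulate_breeding <- function(phenology, params, seed = 1,
                              year_effects = NULL, sst = NULL) {
  stopifnot(inherits(params, "pm_params"))
  years <- sort(unique(phenology$year))
  if (is.null(year_effects))
    year_effects <- draw_year_effects(params, years, seed)
  if (nrow(year_effects) != length(years))
    stop("year_effects must have one row per simulated year")
  if (params$beta_W_sst != 0 && is.null(sst))
    stop("sst series required when beta_W_sst != 0")

  xbar <- tapply(phenology$lay_date, phenology$year, mean)
  yi <- match(phenology$year, years)
  rel <- phenology$lay_date - xbar[yi]
  xbar_c <- xbar - mean(xbar)
  yc <- years - mean(years)
  sst_c <- if (is.null(sst)) rep(0, length(years)) else {
    s <- sst$sst[match(years, sst$year)]
    s - mean(s)
  }
  w_slope <- params$beta_W + year_effects[, "W_Sh"] +
    params$beta_W_year * yc + params$beta_W_sst * sst_c
  eta <- params$mu + year_effects[yi, "B_Sh"] + params$beta_B * xbar_c[yi] +
    w_slope[yi] * rel + params$gamma * rel^2
  withr::with_seed(seed + 1000003L, {
    eta <- eta + rnorm(length(eta), 0, params$resid_sd)
    n_fledged <- rbinom(length(eta), size = 4, prob = plogis(eta))
  })
  out <- phenology
  out$n_fledged <- as.integer(n_fledged)
  out
}

#' Simulate regurgitate diet samples
#'
#' Collection dates are drawn Normal around the annual mean lay date plus
#' a configurable offset, truncated to the April--July field season, so
#' that median collection date tracks median lay date across years. The
#' latent offset-logit proportion of 1+ group sandeels declines linearly
#' with relative collection date, with year-varying intercepts (B_Sa) and
#' slopes (W_Sa); the observed proportion is the inverse offset-logit of
#' the latent value plus residual noise, clipped to [0, 1].
#'
#' @param phenology data.frame from [simulate_phenology()] (supplies
#'   annual mean lay dates).
#' @param params a [simulation_params()] object.
#' @param seed integer seed (use the same seed as [simulate_breeding()]
#'   to share the joint year-effect draw).
#' @param year_effects optional matrix from [draw_year_effects()].
#' @return data.frame with columns `year`, `sample_date`, `prop_oneplus`.
#' @export
simulate_diet <- function(phenology, params, seed = 1, year_effects = NULL) {
  stopifnot(inherits(params, "pm_params"))
  if (params$samples_per_year[1] < 1)
    stop("samples_per_year min must be >= 1")
  years <- sort(unique(phenology$year))
  if (is.null(year_effects))
    year_effects <- draw_year_effects(params, years, seed)
  xbar <- tapply(phenology$lay_date, phenology$year, mean)
  season <- c(90, 211)                    # April 1 .. July 31, Jan 1 = 0
  withr::with_seed(seed + 2000029L, {
    out <- do.call(rbind, lapply(seq_along(years), function(i) {
      m <- params$samples_per_year[1] +
        sample.int(params$samples_per_year[2] - params$samples_per_year[1] +
                     1L, 1) - 1L
      centre <- xbar[i] + params$diet_date_offset
      d <- rnorm(m, centre, params$diet_date_sd)
      d <- pmin(pmax(d, season[1]), season[2])
      d <- as.integer(round(d))
      rel <- d - mean(d)
      lat <- params$diet_mu + year_effects[i, "B_Sa"] +
        (params$diet_within_slope + year_effects[i, "W_Sa"]) * rel +
        rnorm(m, 0, params$diet_resid_sd)
      data.frame(year = years[i], sample_date = d,
                 prop_oneplus = inv_logit_offset(lat))
    }))
  })
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' Orchestrates [simulate_sst()], [simulate_phenology()],
#' [draw_year_effects()], [simulate_breeding()] and [simulate_diet()]
#' under one master seed, returning all tables plus a ground-truth record
#' (the parameters, the realised year effects, and the seed) for
#' parameter-recovery testing. Optionally writes `breeding.csv`,
#' `env.csv`, `diet.csv` and `truth.json` to a directory.
#'
#' @param params a [simulation_params()] object.
#' @param seed master integer seed.
#' @param dir optional output directory; created if missing.
#' @return list with elements `breeding`, `env`, `diet`, `truth`.
#' @export
simulate_study <- function(params = simulation_params(), seed = 1,
                           dir = NULL) {
  sst <- simulate_sst(params, seed)
  phen <- simulate_phenology(params, sst, seed)
  years <- sort(unique(phen$year))
  eff <- draw_year_effects(params, years, seed)
  breeding <- simulate_breeding(phen, params, seed, year_effects = eff,
                                sst = sst)
  diet <- simulate_diet(phen, params, seed, year_effects = eff)
  # population size: log-normal around a slow decline, purely contextual
  withr::with_seed(seed + 3000017L, {
    yc <- sst$year - mean(sst$year)
    pop <- round(exp(log(1200) - 0.01 * yc + rnorm(length(yc), 0, 0.15)))
  })
  env <- data.frame(year = sst$year, sst = sst$sst, sst_prev = sst$sst_prev,
                    population_size = as.integer(pop))
  truth <- list(params = unclass(params)[setdiff(names(params), "cross_cov")],
                cross_cov = unname(params$cross_cov),
                year_effects = as.data.frame(cbind(year = years, eff)),
                seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write.csv(breeding, file.path(dir, "breeding.csv"), row.names = FALSE)
    write.csv(env, file.path(dir, "env.csv"), row.names = FALSE)
    write.csv(diet, file.path(dir, "diet.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(breeding = breeding, env = env, diet = diet, truth = truth)
}
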