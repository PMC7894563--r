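test_that("noise-free SST series is the constant mean", {
  p <- tiny_params(sst_trend = 0, sst_sd = 0)
  s <- simulate_sst(p, seed = 1)
  expect_equal(s$sst, rep(p$sst_mean, p$n_years))
  expect_equal(s$sst_prev, rep(p$sst_mean, p$n_years))
})

test_that("sst_prev is the lag-1 value of the sst column", {
  s <- simulate_sst(tiny_params(), seed = 3)
  expect_equal(s$sst_prev[-1], s$sst[-nrow(s)])
})

test_that("non-stationary AR coefficients are rejected", {
  expect_error(simulation_params(sst_ar_phi = 1), "stationarity")
  expect_error(simulation_params(sst_ar_phi = -1.2), "stationarity")
})

test_that("simulated AR(1) noise has the configured lag-1 autocorrelation", {
  p <- simulation_params(n_years = 10000, sst_ar_phi = 0.27, sst_trend = 0,
                         gap_years = integer(0))
  s <- simulate_sst(p, seed = 11)
  r <- acf(s$sst - mean(s$sst), lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r - 0.27), 0.02)
})

test_that("noise-free phenology means equal the intercept and centring is exact", {
  p <- tiny_params(laydate_trend = 0, laydate_sst_slope = 0,
                   laydate_year_sd = 0)
  phen <- simulate_phenology(p, simulate_sst(p, seed = 1), seed = 1)
  means <- tapply(phen$lay_date, phen$year, mean)
  # annual means are the intercept up to the integer rounding of dates
  expect_true(all(abs(means - p$laydate_intercept) <=
                    3 * p$laydate_within_sd / sqrt(30)))
  rel <- phen$lay_date - means[as.character(phen$year)]
  relsum <- as.numeric(tapply(rel, phen$year, sum))
  expect_equal(relsum, rep(0, length(relsum)), tolerance = 1e-12)
})

test_that("gap years are dropped and nest counts respect the range", {
  p <- simulation_params(n_years = 8, start_year = 2000,
                         gap_years = c(2002, 2005),
                         nests_per_year = c(5, 9))
  phen <- simulate_phenology(p, simulate_sst(p, seed = 2), seed = 2)
  expect_false(any(phen$year %in% c(2002, 2005)))
  counts <- table(phen$year)
  expect_true(all(counts >= 5 & counts <= 9))
  expect_equal(length(counts), 6)
})

test_that("lay-date trend is recovered across seeds", {
  p <- simulation_params(n_years = 30, laydate_trend = -0.94,
                         laydate_sst_slope = 0, gap_years = integer(0),
                         nests_per_year = c(40, 40))
  slopes <- sapply(1:40, function(s) {
    phen <- simulate_phenology(p, simulate_sst(p, seed = s), seed = s)
    m <- tapply(phen$lay_date, phen$year, mean)
    fit_ols(as.numeric(names(m)), as.numeric(m))$slope
  })
  expect_lt(abs(mean(slopes) + 0.94), 2 * sd(slopes) / sqrt(length(slopes)))
})

test_that("null breeding simulation fledges two chicks on average", {
  p <- simulation_params(n_years = 5, nests_per_year = c(2000, 2000),
                         gap_years = integer(0), mu = 0, beta_B = 0,
                         beta_W = 0, gamma = 0, sigma2_int = 0,
                         sigma2_slope = 0, resid_sd = 0)
  phen <- simulate_phenology(p, simulate_sst(p, seed = 4), seed = 4)
  br <- simulate_breeding(phen, p, seed = 4)
  expect_true(all(br$n_fledged %in% 0:4))
  expect_lt(abs(mean(br$n_fledged) - 2), 0.05)
})

test_that("identical seeds reproduce identical tables", {
  p <- tiny_params()
  a <- simulate_study(p, seed = 9)
  b <- simulate_study(p, seed = 9)
  expect_identical(a$breeding, b$breeding)
  expect_identical(a$diet, b$diet)
  expect_identical(a$env, b$env)
  c <- simulate_study(p, seed = 10)
  expect_false(identical(a$breeding, c$breeding))
})

test_that("a non-PSD cross covariance is rejected by name", {
  cc <- diag(4); cc[1, 2] <- cc[2, 1] <- 2
  expect_error(simulation_params(cross_cov = cc), "cross_cov")
})

test_that("diet proportions are flat at the inverse offset-logit of the intercept", {
  p <- tiny_params(diet_within_slope = 0, diet_sigma2_int = 0,
                   diet_sigma2_slope = 0, diet_resid_sd = 0,
                   diet_mu = 0.8)
  phen <- simulate_phenology(p, simulate_sst(p, seed = 5), seed = 5)
  diet <- simulate_diet(phen, p, seed = 5)
  expect_equal(diet$prop_oneplus,
               rep(inv_logit_offset(0.8), nrow(diet)), tolerance = 1e-12)
  expect_true(all(diet$prop_oneplus >= 0 & diet$prop_oneplus <= 1))
})

test_that("breeding and diet share one joint year-effect draw per seed", {
  p <- tiny_params()
  phen <- simulate_phenology(p, simulate_sst(p, seed = 6), seed = 6)
  years <- sort(unique(phen$year))
  e1 <- draw_year_effects(p, years, seed = 6)
  e2 <- draw_year_effects(p, years, seed = 6)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(length(years), 4L))
})

test_that("simulate_study writes the full csv/json bundle", {
  dir <- tempfile("simout_")
  sim <- simulate_study(tiny_params(), seed = 2, dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("breeding.csv", "env.csv", "diet.csv", "truth.json")))))
  rt <- read_breeding_csv(file.path(dir, "breeding.csv"))
  expect_equal(nrow(rt), nrow(sim$breeding))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 2)
  expect_equal(nrow(truth$year_effects), length(unique(sim$breeding$year)))
  unlink(dir, recursive = TRUE)
})
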