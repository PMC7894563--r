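test_that("offset logit has its closed-form values at 0, 0.5 and 1", {
  expect_identical(logit_offset(0.5), 0)
  expect_equal(logit_offset(0), -log(101), tolerance = 1e-15)
  expect_equal(logit_offset(1), log(101), tolerance = 1e-15)
  expect_equal(logit_offset(0), -4.61512, tolerance = 1e-5)
})

test_that("offset logit is antisymmetric, monotone and invertible", {
  p <- seq(0, 1, by = 0.01)
  expect_equal(logit_offset(p), -logit_offset(1 - p), tolerance = 1e-12)
  expect_true(all(diff(logit_offset(p)) > 0))
  inner <- seq(0.001, 0.999, length.out = 201)
  expect_equal(inv_logit_offset(logit_offset(inner)), inner,
               tolerance = 1e-12)
  # beyond the representable range the inverse clips to [0, 1]
  expect_identical(inv_logit_offset(c(-10, 10)), c(0, 1))
  expect_error(logit_offset(1.2), "0, 1")
  expect_error(logit_offset(-0.1), "0, 1")
})

test_that("constant proportions give slopes indistinguishable from zero", {
  p <- tiny_params(diet_within_slope = 0, diet_sigma2_int = 0,
                   diet_sigma2_slope = 0, diet_resid_sd = 0.05,
                   diet_mu = 0.4)
  phen <- simulate_phenology(p, simulate_sst(p, seed = 8), seed = 8)
  diet <- simulate_diet(phen, p, seed = 8)
  fit <- fit_diet_model(diet, "sandeel_core", mcmc = quick_mcmc(8))
  cf <- summarize_posterior(fit)
  for (par in c("mean_sample_date", "rel_date")) {
    row <- cf[cf$parameter == par, ]
    expect_false(row$significant)
    expect_lt(abs(row$mean), 0.01)
  }
})

test_that("within-year diet slope is recovered from a faithful regime", {
  p <- mild_diet_params(n_years = 15, nests_per_year = c(30, 30),
                        gap_years = integer(0))
  ests <- sapply(1:6, function(s) {
    phen <- simulate_phenology(p, simulate_sst(p, seed = s), seed = s)
    diet <- simulate_diet(phen, p, seed = s)
    fit <- fit_diet_model(diet, "sandeel_core", mcmc = quick_mcmc(s))
    cf <- summarize_posterior(fit)
    c(est = cf$mean[cf$parameter == "rel_date"],
      lo = cf$lower[cf$parameter == "rel_date"],
      hi = cf$upper[cf$parameter == "rel_date"])
  })
  expect_lt(abs(mean(ests["est", ]) + 0.095),
            max(3 * sd(ests["est", ]) / sqrt(6), 0.01))
  expect_gte(mean(ests["lo", ] <= -0.095 & ests["hi", ] >= -0.095), 0.5)
})

test_that("zero among-year variance concentrates the intercept variance near zero", {
  p <- mild_diet_params(n_years = 20, nests_per_year = c(30, 30),
                        gap_years = integer(0), diet_sigma2_int = 0,
                        diet_sigma2_slope = 0)
  phen <- simulate_phenology(p, simulate_sst(p, seed = 21), seed = 21)
  diet <- simulate_diet(phen, p, seed = 21)
  fit <- fit_diet_model(diet, "sandeel_core", mcmc = quick_mcmc(21))
  cf <- summarize_posterior(fit)
  expect_lt(cf$upper[cf$parameter == "var_intercept"], 0.5)
  expect_lt(cf$upper[cf$parameter == "var_slope"], 0.01)
})

test_that("sandeel year variant carries the year interaction and a null is covered", {
  p <- mild_diet_params(n_years = 15, nests_per_year = c(30, 30),
                        gap_years = integer(0))
  covered <- sapply(1:5, function(s) {
    phen <- simulate_phenology(p, simulate_sst(p, seed = 30 + s),
                               seed = 30 + s)
    diet <- simulate_diet(phen, p, seed = 30 + s)
    fit <- fit_diet_model(diet, "sandeel_year", mcmc = quick_mcmc(30 + s))
    cf <- summarize_posterior(fit)
    expect_true(all(c("year_c", "rel_date:year_c") %in% cf$parameter))
    row <- cf[cf$parameter == "rel_date:year_c", ]
    row$lower <= 0 && row$upper >= 0
  })
  expect_gte(mean(covered), 0.8)
})

test_that("single-sample years are tolerated with a message", {
  diet <- data.frame(year = c(2000, 2000, 2001, 2001, 2002),
                     sample_date = c(120, 140, 125, 150, 130),
                     prop_oneplus = c(0.9, 0.5, 0.8, 0.4, 0.7))
  expect_message(fit_diet_model(diet, "sandeel_core",
                                mcmc = quick_mcmc(1, n = 600, burn = 100,
                                                  thin = 1)),
                 "single sample")
})

test_that("diet residual variance is estimated, not fixed", {
  p <- mild_diet_params(n_years = 12, nests_per_year = c(30, 30),
                        gap_years = integer(0), diet_resid_sd = 0.5)
  phen <- simulate_phenology(p, simulate_sst(p, seed = 13), seed = 13)
  diet <- simulate_diet(phen, p, seed = 13)
  fit <- fit_diet_model(diet, "sandeel_core", mcmc = quick_mcmc(13))
  cf <- summarize_posterior(fit)
  row <- cf[cf$parameter == "sigma2_resid", ]
  expect_gt(row$mean, 0.15)
  expect_lt(row$mean, 0.45)
})
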