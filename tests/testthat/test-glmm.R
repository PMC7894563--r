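test_that("build_design centres relative lay date exactly within years", {
  breeding <- data.frame(year = rep(2001, 3), nest_id = paste0("n", 1:3),
                         lay_date = c(100, 110, 120),
                         n_fledged = c(1, 2, 3))
  breeding <- rbind(breeding,
                    data.frame(year = rep(2002, 2), nest_id = c("a", "b"),
                               lay_date = c(90, 130), n_fledged = c(0, 4)),
                    data.frame(year = rep(2003, 2), nest_id = c("c", "d"),
                               lay_date = c(105, 115), n_fledged = c(2, 2)))
  d <- build_design(breeding, variant = "core")
  expect_equal(d$X[1:3, "rel_date"], c(-10, 0, 10), ignore_attr = TRUE)
  sums <- as.numeric(tapply(d$X[, "rel_date"], breeding$year, sum))
  expect_equal(sums, rep(0, 3), tolerance = 1e-12)
  expect_equal(d$successes + d$failures, rep(4L, nrow(breeding)),
               ignore_attr = TRUE)
  expect_equal(d$X[, "rel_date_sq"], d$X[, "rel_date"]^2, ignore_attr = TRUE)
})

test_that("within-year relative dates sum to zero on any simulated input", {
  for (s in 1:5) {
    sim <- simulate_study(tiny_params(), seed = s)
    d <- build_design(sim$breeding, variant = "core")
    sums <- tapply(d$X[, "rel_date"], sim$breeding$year, sum)
    expect_lt(max(abs(sums)), 1e-9)
  }
})

test_that("the year variant adds exactly the centred year and its interaction", {
  sim <- simulate_study(tiny_params(), seed = 1)
  ctx <- build_year_context(sim$breeding, sim$env)
  core <- build_design(sim$breeding, ctx, variant = "core")
  yr <- build_design(sim$breeding, ctx, variant = "year")
  expect_equal(setdiff(colnames(yr$X), colnames(core$X)),
               c("year_c", "rel_date:year_c"))
  expect_equal(ncol(yr$X), ncol(core$X) + 2)
  sst <- build_design(sim$breeding, ctx, variant = "sst_current")
  expect_equal(setdiff(colnames(sst$X), colnames(core$X)),
               c("year_c", "sst", "rel_date:sst"))
  pop <- build_design(sim$breeding, ctx, variant = "core_popsize")
  expect_equal(setdiff(colnames(pop$X), colnames(core$X)), "log_popsize")
})

test_that("design validation names offending years and rows", {
  sim <- simulate_study(tiny_params(), seed = 2)
  ctx <- build_year_context(sim$breeding, sim$env)
  ctx2 <- ctx[ctx$year != sim$breeding$year[1], ]
  expect_error(build_design(sim$breeding, ctx2, variant = "year"),
               as.character(sim$breeding$year[1]))
  bad <- sim$breeding
  bad$n_fledged[7] <- 5L
  expect_error(build_design(bad, variant = "core"), "7")
  expect_error(build_design(bad[, -3], variant = "core"), "lay_date")
})

test_that("replacement clutches are dropped with a message", {
  breeding <- data.frame(year = rep(2000:2002, each = 3),
                         nest_id = paste0("n", 1:9),
                         lay_date = rep(c(100, 110, 120), 3),
                         n_fledged = rep(2L, 9),
                         attempt = c(1, 1, 2, 1, 1, 1, 2, 1, 1))
  expect_message(d <- build_design(breeding, variant = "core"),
                 "2 replacement-clutch")
  expect_equal(d$n, 7)
})

test_that("posterior summaries follow draw quantiles", {
  draws <- matrix(rep(c(3, 3), 200), ncol = 1,
                  dimnames = list(NULL, "a"))
  s <- summarize_posterior(draws)
  expect_equal(s$mean, 3)
  expect_equal(s$lower, 3)
  expect_true(s$significant)
  draws2 <- matrix(rep(c(-1, 1), 100), ncol = 1,
                   dimnames = list(NULL, "b"))
  s2 <- summarize_posterior(draws2)
  expect_false(s2$significant)
  set.seed(1)
  draws3 <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "z"))
  s3 <- summarize_posterior(draws3)
  expect_equal(s3$lower, -1.96, tolerance = 0.04)
  expect_equal(s3$upper, 1.96, tolerance = 0.04)
})

test_that("vertex arithmetic matches -b/(2a) on degenerate draws", {
  post <- list(draws = coda::mcmc(matrix(
    rep(c(-0.026, -0.0007), each = 200), ncol = 2,
    dimnames = list(NULL, c("rel_date", "rel_date_sq")))))
  class(post) <- "pm_posterior"
  v <- vertex(post)
  expect_equal(v$estimate, -18.57142857142857, tolerance = 1e-9)
  expect_equal(v$ci_low, v$estimate, tolerance = 1e-9)
  post$draws[, "rel_date"] <- 0
  expect_equal(vertex(post)$estimate, 0)
})

test_that("zero-quadratic draws are excluded from the vertex with a warning", {
  set.seed(2)
  m <- cbind(rel_date = rnorm(100, -0.02, 0.001),
             rel_date_sq = c(rep(0, 10), rnorm(90, -8e-4, 1e-4)))
  post <- structure(list(draws = coda::mcmc(m)), class = "pm_posterior")
  expect_warning(v <- vertex(post), "zero quadratic")
  expect_equal(v$n_excluded, 10)
})

test_that("optimum sensitivity reduces to the timing trend under a null interaction", {
  m <- cbind("rel_date:year_c" = rep(0, 400),
             rel_date_sq = rep(-7e-4, 400))
  post <- structure(list(draws = coda::mcmc(m)), class = "pm_posterior")
  tr <- structure(list(slope = -0.94, slope_se = 0.33, intercept = 127,
                       p_value = 0.009, phi = 0.15, n = 28),
                  class = "pm_trend")
  B <- optimum_sensitivity(post, tr, "year")
  expect_identical(B$B, -0.94)
  expect_equal(B$decomposition$optimum_shift, 0)
  tr0 <- structure(list(slope = 0, slope_se = 0, intercept = 0,
                        p_value = 1, phi = 0, n = 28), class = "pm_trend")
  expect_identical(optimum_sensitivity(post, tr0, "year")$B, 0)
  expect_error(optimum_sensitivity(post, tr, "sst"), "sst_current")
})

test_that("null data give fixed-effect intervals covering zero", {
  p <- tiny_params(mu = 0, beta_B = 0, beta_W = 0, gamma = 0,
                   sigma2_int = 0.05, sigma2_slope = 1e-5)
  hits <- sapply(1:5, function(s) {
    sim <- simulate_study(p, seed = 40 + s)
    fit <- fit_core_quick(sim, 40 + s)
    cf <- summarize_posterior(fit, c("mean_lay_date", "rel_date",
                                     "rel_date_sq"))
    all(cf$lower <= 0 & cf$upper >= 0)
  })
  expect_gte(mean(hits), 0.6)
})

test_that("chains are reproducible and seeds change them", {
  sim <- simulate_study(tiny_params(), seed = 3)
  d <- build_design(sim$breeding, variant = "core")
  f1 <- suppressWarnings(fit_glmm(d, mcmc = quick_mcmc(5, n = 2000, burn = 500)))
  f2 <- suppressWarnings(fit_glmm(d, mcmc = quick_mcmc(5, n = 2000, burn = 500)))
  f3 <- suppressWarnings(fit_glmm(d, mcmc = quick_mcmc(6, n = 2000, burn = 500)))
  expect_identical(as.matrix(f1$draws), as.matrix(f2$draws))
  expect_false(identical(as.matrix(f1$draws), as.matrix(f3$draws)))
})

test_that("posterior means agree with an independent long-run reference chain", {
  p <- simulation_params(n_years = 3, nests_per_year = c(30, 30),
                         gap_years = integer(0))
  sim <- simulate_study(p, seed = 50)
  d <- build_design(sim$breeding, variant = "core")
  short <- suppressWarnings(fit_glmm(d, mcmc = mcmc_settings(8000, 2000, 4,
                                                             seed = 1)))
  long <- suppressWarnings(fit_glmm(d, mcmc = mcmc_settings(80000, 20000, 4,
                                                            seed = 99)))
  for (par in c("(Intercept)", "rel_date", "rel_date_sq")) {
    se <- sqrt(mcse(short$draws[, par], short$ess[par])^2 +
                 mcse(long$draws[, par], long$ess[par])^2)
    expect_lt(abs(mean(short$draws[, par]) - mean(long$draws[, par])),
              3.5 * se)
  }
})

test_that("shifting one year's lay dates leaves within-year estimates unchanged", {
  sim <- simulate_study(tiny_params(), seed = 60)
  shifted <- sim$breeding
  yr <- shifted$year == shifted$year[1]
  shifted$lay_date[yr] <- shifted$lay_date[yr] + 13L
  d1 <- build_design(sim$breeding, variant = "core")
  d2 <- build_design(shifted, variant = "core")
  expect_equal(d1$X[, "rel_date"], d2$X[, "rel_date"])
  f1 <- suppressWarnings(fit_glmm(d1, mcmc = quick_mcmc(7)))
  f2 <- suppressWarnings(fit_glmm(d2, mcmc = quick_mcmc(7)))
  for (par in c("rel_date", "rel_date_sq")) {
    se <- sqrt(mcse(f1$draws[, par], f1$ess[par])^2 +
                 mcse(f2$draws[, par], f2$ess[par])^2)
    expect_lt(abs(mean(f1$draws[, par]) - mean(f2$draws[, par])), 3.5 * se)
  }
})

test_that("slope variance summary tracks the generative value", {
  p <- tiny_params(n_years = 25, nests_per_year = c(60, 60),
                   sigma2_slope = 0.01, sigma2_int = 0.2)
  sim <- simulate_study(p, seed = 70)
  fit <- fit_core_quick(sim, 70)
  sv <- slope_variance(fit)
  expect_gt(sv$estimate, 0.002)
  expect_lt(sv$estimate, 0.05)
  expect_true(sv$ci_low <= 0.01 && sv$ci_high >= 0.01)
})
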