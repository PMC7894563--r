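# Shared fixtures: small, fast parameter sets for fit-based tests.

# compact study: quick to simulate and fit
tiny_params <- function(...) {
  defaults <- list(n_years = 10, nests_per_year = c(30, 30),
                   gap_years = integer(0), samples_per_year = c(10, 20))
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

# diet parameters scaled so the latent offset-logit stays inside
# +/- log(101): the observation map is then faithful and latent-scale
# recovery is meaningful (see the methods vignette on censoring).
mild_diet_params <- function(...) {
  defaults <- list(diet_mu = 0.5, diet_sigma2_int = 1,
                   diet_sigma2_slope = 0.002, diet_resid_sd = 1,
                   diet_date_sd = 10, diet_date_offset = 0,
                   samples_per_year = c(20, 40))
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_params, args)
}

quick_mcmc <- function(seed, n = 5000, burn = 1000, thin = 4) {
  mcmc_settings(n, burn, thin, seed = seed, reduced_scale = TRUE)
}

fit_core_quick <- function(sim, seed, ...) {
  d <- build_design(sim$breeding, variant = "core")
  suppressWarnings(fit_glmm(d, mcmc = quick_mcmc(seed, ...)))
}

# Monte-Carlo standard error of a posterior-mean estimate
mcse <- function(draws, ess) sd(draws) / sqrt(max(ess, 1))
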