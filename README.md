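# phenomatch

Statistical machinery for testing fitness signatures of **trophic
match–mismatch** in seasonally breeding populations, built around a
three-decade seabird case: nest-level breeding success of European shags
regressed on lay date at the population and individual levels, seasonal
shifts in sandeel diet, and the year-level covariance between fitness
and diet.

The package is aimed at statistical ecologists who need the full
pipeline — trend estimation, hierarchical Bayesian random-regression
fits, derived selection statistics, and a synthetic-data generator that
makes every stage testable without any field data.

## The models

**Breeding success.** Fledged count `n ∈ {0..4}` out of a maximum brood
of four, binomial on the latent logit scale:

    z_ij = μ + μ_i + β_B·x̄_i + (β_W + β_Wi)·(x_ij − x̄_i)
           + γ·(x_ij − x̄_i)² + e_ij,   e_ij ~ N(0, 1)

Within-year centring splits lay date into the annual mean `x̄_i`
(between-year axis, slope `β_B`: population-level trend in mean success)
and each nest's deviation (within-year axis, slope `β_W`: directional
selection on timing; quadratic `γ`: stabilising selection). Year-level
random intercepts and slopes `(μ_i, β_Wi)` carry an unstructured 2×2
covariance. Variants add log population size, year, or SST terms with
their relative-date interactions. Derived statistics: the quadratic
vertex `−β_W/(2γ)` (optimum relative lay date, per posterior draw), the
among-year slope variance, and the optimum-advance rate
`B = dx̄/dE − β_int/(2γ)` per unit of environment `E` (year or °C).

**Diet.** The proportion of 1+ group sandeels is mapped by the offset
logit `log((p + 0.01)/(1 − p + 0.01))` (finite at 0 and 1) and modelled
as a Gaussian random regression on annual mean and relative collection
date.

**Bivariate.** Both responses share year-level effects
`(B_Sh, B_Sa, W_Sh, W_Sa)` with an unstructured 4×4 covariance; trophic
mismatch predicts positive cross-trait covariances σ(B_Sa, B_Sh) and
σ(W_Sa, W_Sh).

Fits use a purpose-built Gibbs sampler (C++): conjugate blocked updates
with the fixed effects drawn marginally over the year effects, latent
logits by adaptive Metropolis with periodic slice refresh, fixed unit
residual variance for binomial responses, and parameter-expanded
heavy-tailed priors on covariance scales. Trends use GLS with AR(1)
errors (`nlme`), and correlations use Fisher-z intervals.

## Worked example

```r
library(phenomatch)

params <- simulation_params()              # the emulated colony study
sim    <- simulate_study(params, seed = 1) # breeding, env, diet + truth

design <- build_design(sim$breeding, variant = "core")
fit    <- fit_glmm(design, mcmc = fast_mcmc(seed = 1))

summarize_posterior(fit, c("mean_lay_date", "rel_date", "rel_date_sq"))
#>       parameter          mean       lower        upper significant
#> 1 mean_lay_date -0.0403591278 -0.05501612 -0.024304073        TRUE
#> 2      rel_date -0.0213026363 -0.02726188 -0.016059707        TRUE
#> 3   rel_date_sq -0.0007837082 -0.00104574 -0.000543245        TRUE

vertex(fit)
#> Vertex: -13.97 days relative to annual mean (95% CI -20.82, -9.11)
```

Read: annual mean breeding success declines on the latent logit scale by
0.040 per day of later mean lay date (generative truth −0.035); within
years, success declines by 0.021 per day of relative lay date (truth
−0.026) with a negative quadratic (truth −0.0007), so expected success
peaks about 14 days before the annual mean in this realisation. All
three intervals exclude zero. `run_pipeline()` chains every stage
(trends → model roster → diet → bivariate) and writes `summary.md`,
coefficient CSVs and a machine-readable `report.json`, with recovery
columns when the inputs are simulated.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/phenomatch.R simulate --out data/ --seed 1
Rscript inst/cli/phenomatch.R report --breeding data/breeding.csv \
    --env data/env.csv --diet data/diet.csv --out out/ --fast
```

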