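---
title: "Methods: random-regression models of breeding phenology, fitness and diet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-regression models of breeding phenology, fitness and diet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomatch)
```

## The scientific problem

The match--mismatch hypothesis proposes that consumer fitness declines as
the timing of peak energetic demand drifts away from the seasonal peak of
its resource. phenomatch implements the statistical machinery for testing
fitness signatures of such trophic mismatch in a long-term seabird colony
study: nest-level breeding success of European shags regressed on lay
date at two levels (between years and within years), seasonal diet shifts
in the proportion of 1+ group sandeels, and the year-level covariance
between the two.

The analysis separates two distinct questions through within-subject
centring of lay date:

* **Population level (BSp).** Does *annual mean* breeding success change
  with annual mean lay date (or with year, SST, population size)?
* **Individual level (BSi).** Within a year, do nests that lay earlier
  or later than the colony mean fledge more or fewer chicks? The slope of
  success on *relative* lay date is the directional selection signal; a
  negative quadratic term with an interior peak indicates stabilising
  selection.

## The core model

Each nest-year record carries a lay date $x_{ij}$ (ordinal day, January
1st = 0) and a fledged count $n_{ij} \in \{0,\dots,4\}$, treated as
binomial out of a maximum brood of four (success/failure pair
$n_{ij}$ / $4-n_{ij}$). On the latent logit scale the core model is

$$z_{ij} = \mu + \mu_i + \beta_B\,\bar{x}_i
  + (\beta_W + \beta_{Wi})\,(x_{ij} - \bar{x}_i)
  + \gamma\,(x_{ij} - \bar{x}_i)^2 + e_{ij},$$

where $\bar{x}_i$ is the (grand-mean-centred) annual mean lay date,
$(\mu_i, \beta_{Wi})$ are year-level random intercepts and
relative-lay-date slopes with an unstructured $2\times 2$ covariance, and
$e_{ij}$ is a latent residual with variance fixed at 1 — the standard
identifiability constraint for binomial mixed models with an
observation-level residual. All coefficients are reported on this latent
logit scale.

Model variants add fixed effects to the core roster: log population
size; centred year plus its interaction with relative lay date; or
centred SST (current or previous year) plus centred year and the SST
interaction. The relative-date interaction terms let the strength of
within-year selection change with the covariate.

Derived statistics:

* **Vertex** $v = -\beta_W / (2\gamma)$: the relative lay date at which
  expected success peaks. It is computed *per posterior draw* and then
  summarised; the posterior mean of the ratio is not the ratio of the
  posterior means, and the difference is material when $\gamma$ is small.
* **Among-year slope variance** $\sigma^2_{\beta_W}$: evidence for
  year-to-year variation in the strength of selection.
* **Optimum-advance rate** $B$: writing the optimum in environmental
  state $E$ as $O(E) = \bar{x}(E) + v(E)$ with
  $v(E) = -(\beta_W + \beta_{int}E)/(2\gamma)$, the sensitivity is
  $B = d\bar{x}/dE - \beta_{int}/(2\gamma)$. The first term is the
  (GLS) trend of mean timing on $E$; the second is evaluated per draw.
  The credible interval combines draw quantiles with the trend slope's
  sampling SE in quadrature, a pragmatic fusion of frequentist and
  posterior uncertainty.

## Diet and the bivariate model

The proportion of 1+ group sandeels among sandeels in a regurgitate is
mapped to an unbounded scale by the offset logit
$g(p) = \log\{(p + 0.01)/(1 - p + 0.01)\}$, finite at 0 and 1 by
construction. The diet models are Gaussian random regressions of $g(p)$
on annual mean and relative collection date (or year and its
interaction), with year-level random intercepts and slopes and an
estimated residual variance.

The bivariate model stacks both responses. Each year carries a 4-vector
of effects $(B_{Sh}, B_{Sa}, W_{Sh}, W_{Sa})$ — intercept and
within-year slope deviations for the shag fitness trait and the sandeel
diet trait — with an unstructured $4\times4$ covariance $\Sigma$. Under
trophic mismatch one predicts $\sigma(B_{Sa}, B_{Sh}) > 0$ (good sandeel
years are good breeding years) and $\sigma(W_{Sa}, W_{Sh}) > 0$ (years
with steep within-season diet decline show steep within-season fitness
decline). In the bivariate fit relative timing for *both* traits is
centred on the annual mean lay date, so the diet trait's intercept and
slope deviations are expressed in the fitness trait's timing frame. A
consequence worth noting when validating against simulations: generative
diet parameters stated in the collection-date frame transform when
re-expressed in the lay-date frame (the intercept absorbs
slope-times-offset terms), but cross-trait covariances between
corresponding terms are invariant, which is what the mismatch
predictions concern.

## Sampler

All hierarchical models are fitted by a purpose-built Gibbs sampler
(C++): every conditional is conjugate except the latent logit values,
which are updated by adaptive random-walk Metropolis steps (adaptation
during burn-in only, targeting 0.44 acceptance) with a slice-sampling
refresh every 20th iteration. Two blocking choices matter:

* **Fixed effects are drawn with the year effects integrated out**
  (Woodbury identity on the year-block marginal covariance), and the
  year effects are then redrawn conditional on the new fixed effects.
  Without this, a fixed effect and the mean of its random deviations
  form a likelihood ridge along which elementwise Gibbs mixes
  arbitrarily slowly; with it, effective sample sizes for fixed effects
  approach the retained draw count.
* **The covariance matrix is updated as one inverse-Wishart draw**, so
  every retained $\Sigma$ is symmetric positive definite by
  construction — entrywise updates could leave the cone.

Random-effect covariances get a parameter-expanded prior by default:
$\Sigma = \Lambda \Psi \Lambda^\top$ with working scales
$\lambda_r \sim N(0, 25^2)$ and $\Psi \sim \mathrm{IW}(k+1, I_k)$,
inducing heavy-tailed marginals on the variance scales that mix well
near zero — important here because the among-year slope variance is
genuinely tiny (order $10^{-4}$). Fixed effects get independent
$N(0, 10^8)$ priors. For Gaussian responses the residual variance gets a
scaled inverse-chi-squared prior with $\nu = 0.002$; for binomial
responses it is fixed at 1 and immutable. A plain proper inverse-Wishart
prior (`use_px = FALSE`) is available and is what the
simulation-based-calibration checks use, since it can be sampled from
directly.

Default chain settings are 100,000 iterations, 10,000 burn-in, thinning
10 (400,000 / 40,000 for the bivariate model); `fast_mcmc()` is a
reduced 10,000-iteration profile for tests and simulation studies,
flagged `reduced_scale` in the posterior metadata. Convergence is
monitored by effective sample sizes; parameters below 100 effective
draws trigger a recorded warning.

Significance of fixed effects is exclusively the 95%
credible-interval-excludes-zero rule; no p-values are attached to
Bayesian fits. For data-scale plots the latent prediction is divided by
$\sqrt{1 + c^2\sigma^2_e}$ with $c = 16\sqrt{3}/(15\pi)$ before the
logistic map — the standard logistic approximation for marginalising a
latent Gaussian residual (here $\sigma^2_e = 1$).

## Trends

Temporal trends in SST and mean lay date use generalised least squares
with AR(1) errors, the AR coefficient estimated jointly by REML
(`nlme::gls`); the correlation is $\phi^{|t_1-t_2|}$ in the *year*
covariate, so missing years do not shorten lags. With $\phi$ fixed the
fit is computed directly by prewhitening and reduces exactly to OLS at
$\phi = 0$; on degenerate (perfect-fit) inputs where the REML iteration
fails, $\phi$ is profiled over a grid of prewhitened fits. Two-sided
p-values use $t_{n-2}$. The lay-date response to SST uses OLS, and the
collection-date/lay-date association uses the Pearson correlation with a
Fisher-z interval ($\pm 1.96/\sqrt{n-3}$).

## The synthetic study generator

`simulation_params()` defaults describe the emulated colony study: 30
breeding seasons from 1987 with 1993 and 2003 missing, 35--266 nests per
year, SST mean 5.94 °C warming at 0.02 °C/year over AR(1) noise
($\phi = 0.27$, innovation SD 0.35 °C chosen to match the observed
5.08--6.78 °C range), mean lay date 127 advancing at −0.94 days/year and
responding to SST anomalies at −6.3 days/°C, and latent-logit fledging
with $\beta_B = -0.035$, $\beta_W = -0.026$, $\gamma = -0.0007$,
year-intercept variance 0.3, slope variance $10^{-4}$ and a unit latent
residual. Diet samples decline within season at −0.095 logit/day with
among-year intercept and slope variances 6.46 and 0.015. Year effects
for fitness and diet are drawn jointly from a 4×4 covariance
(block-diagonal by default; `cross_cov` sets cross-trait links).

Free choices the study does not pin down, fixed once here: within-year
lay-date spread is Gaussian with SD 12 days (a symmetric spread is what
within-year centring implicitly assumes); annual-mean lay-date noise has
SD 6 days; collection dates are Normal around the annual mean lay date
plus 30 days, SD 20, truncated to the April--July field season (the
study reports only the observed correlation of about 0.86 between median
collection and lay dates, not a mechanism — these settings reproduce a
correlation of that order); diet intercept 1.4 and residual SD 1.5 on
the offset-logit scale. Dates are written as integer ordinal days.

**What the generator does and does not emulate.** It reproduces the
year-level random-regression structure, binomial fledging, AR(1)
environmental forcing and gap years. It does not simulate individual
bird identity, spatial plot structure, replacement clutches, or lay-date
measurement error (the field protocol's up-to-4-day overestimate is not
modelled — nor was it in the original analysis). Passing recovery tests
therefore validate the estimator under the assumed data-generating
process, not robustness to these unmodelled features.

**Censoring at the proportion boundaries.** The diet observation map is
the inverse offset logit clipped to [0, 1]: latent values beyond
$\pm\log(101) \approx \pm 4.615$ are censored at proportions of exactly
0 or 1. At the full study-scale variances (intercept SD
$\sqrt{6.46} \approx 2.5$, slope SD $\sqrt{0.015} \approx 0.12$/day) a
substantial fraction of year-seasons saturate, exactly as real
proportion data do (April samples sit at 1.00); latent-scale parameter
recovery is then attenuated toward zero by construction, not by a defect
of the estimator. Recovery tests therefore use non-saturating parameter
sets; fits at the defaults should be read as estimates of the censored
process.

## Testing conventions and problem sizes

The test suite validates the sampler itself, not only point estimates:

* **Reference-chain agreement** on a small dataset: short default-prior
  chains match a 10×-longer independently seeded chain within
  Monte-Carlo error.
* **Simulation-based calibration**: with a fully proper prior
  (`use_px = FALSE`), 200 draws of (parameters, data) from the prior
  predictive are each fitted at reduced chain length (99 retained,
  near-independent draws) on a 10-year × 30-nest design; ranks of the
  truths in their posteriors are checked for uniformity by a
  $\chi^2$ test at $\alpha = 0.01$ for the intercept, the
  within-year slope, the quadratic and the intercept variance.
* **Coverage**: 50 replicates of the 30-year × 150-nest study at the
  default generative values, fitted with the fast profile; 95% interval
  coverage of each core parameter is required to sit in [0.88, 1].
* **Nulls**: independent traits must yield cross-trait covariance
  intervals covering zero in at least 90% of 30 reduced-scale bivariate
  fits; vertex and optimum-advance formulas are checked exactly on
  degenerate posteriors.

Replicate counts, the toy design sizes and the reduced chain profiles
are the package's chosen testing scale: large enough for the binomial
coverage bounds being asserted, small enough to keep the suite
routinely runnable.

## Numerical notes and limitations

* Exact centring: relative dates are computed from the realised annual
  means, so they sum to zero within year to machine precision by
  construction.
* Vertex draws with $\gamma = 0$ exactly are excluded (counted, warned
  above 5%); with continuous posteriors this is measure-zero.
* The optimum-advance decomposition assumes the interaction enters the
  optimum linearly; its agreement with alternative derivations of the
  temperature-based sensitivity is not established, and SST-based $B$
  values should be read as indicative.
* Years with a single diet sample have relative date exactly 0 and
  inform intercepts only; this is logged, not fatal.
* The latent-logit/fixed-residual parameterisation matters when
  comparing coefficients with other software: a binomial GLMM without
  the unit observation-level residual targets a different latent scale.
* No Poisson-family refits, no individual-level pedigree structure, no
  information-criterion model comparison: out of scope by design.
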