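// Gibbs sampler for hierarchical (generalised) linear mixed models with
// year-level random regression effects, supporting mixed binomial /
// Gaussian responses in one stacked model.
//
// Model, per observation j in grouping unit (year) i:
//   l_j = x_j' beta + z_j' b_i + e_j
// Binomial rows:  y_j ~ Binomial(size_j, logistic(l_j)), e_j ~ N(0, v_b)
//   with v_b fixed (default 1): l_j is a latent value updated by
//   adaptive Metropolis steps with a periodic slice-sampling refresh
//   (adaptation runs during burn-in only, so the post-burn-in kernel is
//   a fixed, exact MCMC kernel).
// Gaussian rows:  l_j = y_j observed, e_j ~ N(0, sigma2_e) with sigma2_e
//   given a scaled inverse-chi-squared (inverse-Wishart) prior.
// Random effects: b_i ~ MVN(0, Sigma), Sigma unstructured k x k.
//   Either a plain inverse-Wishart prior on Sigma, or a parameter-expanded
//   prior: b_i = Lambda u_i with Lambda = diag(lambda), lambda ~ N(0,
//   px_var I), u_i ~ MVN(0, Psi), Psi ~ IW(nu0, V0); then
//   Sigma = Lambda Psi Lambda'. The expanded form induces a heavy-tailed
//   marginal prior on the variance scales and mixes well near zero
//   variance.
// Fixed effects: beta_m ~ N(0, prior_var_m), independent.
//
// All conditionals except the latent logits are conjugate. All
// randomness comes from R's RNG so set.seed() in R makes chains
// reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log p(l | y, size, m, v): binomial logit likelihood times Gaussian
// pseudo-prior centred at the linear predictor m with variance v.
static inline double latent_logpost(double l, double y, double size,
                                    double m, double v) {
  double ll;
  if (l > 0) {
    ll = y * l - size * (l + std::log1p(std::exp(-l)));
  } else {
    ll = y * l - size * std::log1p(std::exp(l));
  }
  double d = l - m;
  return ll - 0.5 * d * d / v;
}

// Univariate slice sampler (Neal 2003, stepping out + shrinkage).
static double slice_update(double l0, double y, double size, double m,
                           double v) {
  const double w = 1.5;
  const int max_steps = 50;
  double f0 = latent_logpost(l0, y, size, m, v);
  double logu = f0 - R::exp_rand();
  double left = l0 - w * unif_rand();
  double right = left + w;
  int cnt = 0;
  while (cnt++ < max_steps && latent_logpost(left, y, size, m, v) > logu)
    left -= w;
  cnt = 0;
  while (cnt++ < max_steps && latent_logpost(right, y, size, m, v) > logu)
    right += w;
  for (int it = 0; it < 100; ++it) {
    double prop = left + unif_rand() * (right - left);
    if (latent_logpost(prop, y, size, m, v) > logu) return prop;
    if (prop < l0) left = prop; else right = prop;
  }
  return l0;  // pathological shrinkage; keep current value
}

// Draw MVN(A^-1 rhs, A^-1) for a (small) SPD precision matrix A.
static arma::vec mvn_prec(const arma::vec &rhs, const arma::mat &A) {
  arma::mat U = arma::chol(arma::symmatu(A));   // A = U'U, U upper
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), rhs));
  arma::vec z(rhs.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = norm_rand();
  return mu + arma::solve(arma::trimatu(U), z);
}

// Inverse-Wishart draw: Psi ~ IW(df, S) via Bartlett on W ~ Wishart(df, S^-1).
static arma::mat riwish(double df, const arma::mat &S) {
  arma::uword k = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(k, k, arma::fill::zeros);
  for (arma::uword i = 0; i < k; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// [[Rcpp::export(name = ".gibbs_engine")]]
List gibbs_engine(const arma::vec &y, const arma::vec &size,
                  const arma::ivec &fam,  // 1 = binomial, 0 = gaussian
                  const arma::mat &X, const arma::uvec &year,
                  const arma::mat &Z, const int n_year,
                  const int n_iter, const int burn_in, const int thin,
                  const arma::vec &beta_prior_var,
                  const bool use_px, const double px_var,
                  const double re_nu, const arma::mat &re_V,
                  const double binom_rvar,
                  const double resid_nu, const double resid_s2) {
  const arma::uword n = y.n_elem;
  const arma::uword p = X.n_cols;
  const arma::uword k = Z.n_cols;

  std::vector<std::vector<arma::uword>> obs(n_year);
  for (arma::uword j = 0; j < n; ++j) obs[year(j)].push_back(j);

  arma::uword n_gauss = 0;
  for (arma::uword j = 0; j < n; ++j) if (fam(j) == 0) ++n_gauss;
  const bool any_gauss = n_gauss > 0;

  // precomputed cross-products, split by residual family
  arma::mat XtX_b(p, p, arma::fill::zeros), XtX_g(p, p, arma::fill::zeros);
  std::vector<arma::mat> Szz_b(n_year, arma::mat(k, k, arma::fill::zeros));
  std::vector<arma::mat> Szz_g(n_year, arma::mat(k, k, arma::fill::zeros));
  std::vector<arma::mat> Sxz_b(n_year, arma::mat(p, k, arma::fill::zeros));
  std::vector<arma::mat> Sxz_g(n_year, arma::mat(p, k, arma::fill::zeros));
  for (arma::uword j = 0; j < n; ++j) {
    const arma::rowvec xr = X.row(j);
    const arma::rowvec zr = Z.row(j);
    if (fam(j) == 1) {
      XtX_b += xr.t() * xr;
      Szz_b[year(j)] += zr.t() * zr;
      Sxz_b[year(j)] += xr.t() * zr;
    } else {
      XtX_g += xr.t() * xr;
      Szz_g[year(j)] += zr.t() * zr;
      Sxz_g[year(j)] += xr.t() * zr;
    }
  }

  // state
  arma::vec beta(p, arma::fill::zeros);
  arma::mat u(n_year, k, arma::fill::zeros);
  arma::vec lambda(k, arma::fill::ones);
  arma::mat Psi = arma::eye(k, k);
  double sigma2_e = 1.0;
  if (any_gauss) {
    double s = 0, ss = 0;
    for (arma::uword j = 0; j < n; ++j)
      if (fam(j) == 0) { s += y(j); ss += y(j) * y(j); }
    double m = s / n_gauss;
    sigma2_e = std::max(1e-4, ss / n_gauss - m * m);
  }
  arma::vec l(n);
  for (arma::uword j = 0; j < n; ++j) {
    if (fam(j) == 1) {
      double phat = (y(j) + 0.5) / (size(j) + 1.0);
      l(j) = std::log(phat / (1.0 - phat));
    } else {
      l(j) = y(j);
    }
  }
  for (arma::uword i = 0; i < (arma::uword)n_year; ++i)
    for (arma::uword c = 0; c < k; ++c) u(i, c) = 0.1 * norm_rand();

  // storage
  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat beta_draws(n_keep, p);
  arma::mat sigma_draws(n_keep, k * (k + 1) / 2);
  arma::vec sig2e_draws(n_keep);
  arma::mat re_draws(n_keep, n_year * k);
  int keep = 0;

  arma::vec eta_fix(n), eta_re(n);
  double prop_sd = 0.8;  // adapted during burn-in, then frozen
  long acc = 0, tot = 0;

  for (int it = 0; it < n_iter; ++it) {
    const double wb = 1.0 / binom_rvar;
    const double wg = 1.0 / sigma2_e;

    eta_fix = X * beta;
    for (arma::uword j = 0; j < n; ++j) {
      double s = 0;
      for (arma::uword c = 0; c < k; ++c)
        s += Z(j, c) * lambda(c) * u(year(j), c);
      eta_re(j) = s;
    }

    // 1. latent values for binomial rows: adaptive Metropolis with a
    //    periodic slice refresh
    const bool do_slice = (it % 20 == 0);
    for (arma::uword j = 0; j < n; ++j) {
      if (fam(j) != 1) continue;
      const double m = eta_fix(j) + eta_re(j);
      if (do_slice) {
        l(j) = slice_update(l(j), y(j), size(j), m, binom_rvar);
      } else {
        const double prop = l(j) + prop_sd * norm_rand();
        const double dlp = latent_logpost(prop, y(j), size(j), m, binom_rvar) -
          latent_logpost(l(j), y(j), size(j), m, binom_rvar);
        ++tot;
        if (dlp >= 0 || unif_rand() < std::exp(dlp)) { l(j) = prop; ++acc; }
      }
    }
    if (it < burn_in && !do_slice && tot > 0 && (it % 10 == 9)) {
      const double rate = (double)acc / (double)tot;
      prop_sd *= std::exp(0.5 * (rate - 0.44));
      prop_sd = std::min(std::max(prop_sd, 0.05), 10.0);
      acc = 0; tot = 0;
    }

    // 2. fixed effects, with the year effects integrated out (Woodbury):
    //    beta | l, Lambda, Psi ~ the GLS posterior under marginal
    //    covariance W^-1 + Z G Z' with G = Lambda Psi Lambda'. Blocking
    //    beta with the year effects removes the slow ridge between a
    //    fixed effect and the mean of its random deviations.
    {
      arma::mat G = use_px
        ? arma::mat(arma::diagmat(lambda) * Psi * arma::diagmat(lambda))
        : Psi;
      arma::mat A = wb * XtX_b;
      if (any_gauss) A += wg * XtX_g;
      arma::vec xWl(p, arma::fill::zeros);
      std::vector<arma::vec> zWl(n_year, arma::vec(k, arma::fill::zeros));
      for (arma::uword j = 0; j < n; ++j) {
        const double w = (fam(j) == 1) ? wb : wg;
        const double r = w * l(j);
        for (arma::uword m = 0; m < p; ++m) xWl(m) += r * X(j, m);
        for (arma::uword c = 0; c < k; ++c) zWl[year(j)](c) += r * Z(j, c);
      }
      arma::vec rhs = xWl;
      for (int i = 0; i < n_year; ++i) {
        arma::mat S = wb * Szz_b[i] + (any_gauss ? arma::mat(wg * Szz_g[i])
                                                 : arma::mat(k, k, arma::fill::zeros));
        arma::mat B = wb * Sxz_b[i];
        if (any_gauss) B += wg * Sxz_g[i];
        arma::mat C = G * arma::inv(arma::eye(k, k) + S * G);
        A -= B * C * B.t();
        rhs -= B * C * zWl[i];
      }
      A = arma::symmatu(0.5 * (A + A.t()));
      for (arma::uword m = 0; m < p; ++m) A(m, m) += 1.0 / beta_prior_var(m);
      beta = mvn_prec(rhs, A);
      eta_fix = X * beta;
    }

    // 3. unit-level effects immediately after beta (together the two
    //    steps are one joint (beta, u) block draw)
    {
      arma::mat Psi_inv = arma::inv_sympd(arma::symmatu(Psi));
      arma::mat L = arma::diagmat(lambda);
      for (int i = 0; i < n_year; ++i) {
        arma::mat S = wb * Szz_b[i];
        if (any_gauss) S += wg * Szz_g[i];
        arma::mat A = Psi_inv + L * S * L;
        arma::vec rhs(k, arma::fill::zeros);
        for (arma::uword idx : obs[i]) {
          const double w = (fam(idx) == 1) ? wb : wg;
          const double r = w * (l(idx) - eta_fix(idx));
          for (arma::uword c = 0; c < k; ++c)
            rhs(c) += r * Z(idx, c) * lambda(c);
        }
        u.row(i) = mvn_prec(rhs, A).t();
      }
    }

    // 4. working scale parameters (parameter expansion)
    if (use_px) {
      arma::mat A(k, k, arma::fill::zeros);
      arma::vec rhs(k, arma::fill::zeros);
      for (int i = 0; i < n_year; ++i) {
        arma::mat D = arma::diagmat(u.row(i));
        A += D * (wb * Szz_b[i] + wg * Szz_g[i]) * D;
      }
      for (arma::uword j = 0; j < n; ++j) {
        const double w = (fam(j) == 1) ? wb : wg;
        const double r = w * (l(j) - eta_fix(j));
        for (arma::uword c = 0; c < k; ++c)
          rhs(c) += r * Z(j, c) * u(year(j), c);
      }
      A.diag() += 1.0 / px_var;
      lambda = mvn_prec(rhs, A);
    }

    // 5. covariance of unit effects (conjugate inverse-Wishart)
    Psi = riwish(re_nu + n_year, arma::symmatu(re_V + u.t() * u));

    // 6. Gaussian residual variance
    if (any_gauss) {
      double ss = 0;
      for (arma::uword j = 0; j < n; ++j) {
        if (fam(j) == 0) {
          double s = 0;
          for (arma::uword c = 0; c < k; ++c)
            s += Z(j, c) * lambda(c) * u(year(j), c);
          const double r = l(j) - eta_fix(j) - s;
          ss += r * r;
        }
      }
      sigma2_e = (resid_nu * resid_s2 + ss) / R::rchisq(resid_nu + n_gauss);
    }

    if (it >= burn_in && ((it - burn_in) % thin == 0) && keep < n_keep) {
      beta_draws.row(keep) = beta.t();
      arma::mat Sigma = use_px
        ? arma::mat(arma::diagmat(lambda) * Psi * arma::diagmat(lambda))
        : Psi;
      int pos = 0;
      for (arma::uword a = 0; a < k; ++a)
        for (arma::uword b = a; b < k; ++b)
          sigma_draws(keep, pos++) = Sigma(a, b);
      sig2e_draws(keep) = sigma2_e;
      for (int i = 0; i < n_year; ++i)
        for (arma::uword c = 0; c < k; ++c)
          re_draws(keep, i * k + c) = lambda(c) * u(i, c);
      ++keep;
    }
  }

  return List::create(_["beta"] = beta_draws, _["sigma"] = sigma_draws,
                      _["sigma2_e"] = sig2e_draws, _["ranef"] = re_draws,
                      _["n_keep"] = keep);
}
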