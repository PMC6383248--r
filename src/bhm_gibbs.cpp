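// Gibbs sampler for the woman-level hierarchical logistic model
//   y_i ~ Bernoulli(inv_logit(x_i' beta + u[area_i, round_i]))
//   u[k, ] ~ stationary AR(1): u_k1 ~ N(0, sigma^2/(1-rho^2)),
//            u_kt = rho u_k,t-1 + N(0, sigma^2)
// Conditionals for beta and u are Gaussian after Polya-Gamma augmentation
// (Polson, Scott & Windle 2013); rho and sigma move by adaptive
// random-walk Metropolis on atanh / log scales.
//
// All randomness goes through R's RNG so set.seed() gives bit-identical
// chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TRUNC = 0.64;  // Devroye split point for J*(1,z)

// piecewise alternating-series coefficients a_n(x)
static double a_coef(int n, double x) {
  double np = n + 0.5;
  if (x > TRUNC)
    return M_PI * np * std::exp(-np * np * M_PI * M_PI * 0.5 * x);
  return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np * np / x);
}

// P(X <= t) for X ~ InvGauss(mu = 1/z, lambda = 1); stable as z -> 0
static double pigauss(double t, double z) {
  double rt = std::sqrt(t);
  double b = z * rt - 1.0 / rt;
  double a = -(z * rt + 1.0 / rt);
  return R::pnorm(b, 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(a, 0.0, 1.0, 1, 0);
}

// InvGauss(1/z, 1) truncated to (0, t); valid for z >= 0
static double rtigauss(double z, double t) {
  double x;
  if (z < 1.0 / t) {  // mean beyond the truncation point (incl. z = 0)
    for (;;) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  double mu = 1.0 / z;
  for (;;) {
    double nu = norm_rand();
    double y = nu * nu;
    double muy = mu * y;
    x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
    if (x <= 0.0) x = std::numeric_limits<double>::min();
    if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    if (x < t) return x;
  }
}

// one draw from PG(1, z) = J*(1, z/2) / 4
double rpg1(double zin) {
  double z = 0.5 * std::fabs(zin);
  double fz = M_PI * M_PI * 0.125 + 0.5 * z * z;
  double p = (0.5 * M_PI / fz) * std::exp(-fz * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  for (;;) {
    double x;
    if (unif_rand() * (p + q) < p)
      x = TRUNC + exp_rand() / fz;
    else
      x = rtigauss(z, TRUNC);
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;  // accept
      } else {
        s += a_coef(n, x);
        if (y > s) break;  // reject, restart proposal
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector rpg_cpp(int n, NumericVector z) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i % z.size()]);
  return out;
}

// log density of the stationary AR(1) field u (K x T)
static double ar1_logdens(const arma::mat& u, double rho, double sigma) {
  int K = u.n_rows, T = u.n_cols;
  double s2 = sigma * sigma;
  double ld = 0.0;
  double v1 = s2 / (1.0 - rho * rho);
  for (int k = 0; k < K; ++k) {
    ld += -0.5 * std::log(2.0 * M_PI * v1) - u(k, 0) * u(k, 0) / (2.0 * v1);
    for (int t = 1; t < T; ++t) {
      double r = u(k, t) - rho * u(k, t - 1);
      ld += -0.5 * std::log(2.0 * M_PI * s2) - r * r / (2.0 * s2);
    }
  }
  return ld;
}

// tridiagonal stationary AR(1) precision, scaled by 1/sigma^2
static arma::mat ar1_precision(int T, double rho, double sigma) {
  arma::mat Q(T, T, arma::fill::zeros);
  double s2 = sigma * sigma;
  if (T == 1) {
    Q(0, 0) = (1.0 - rho * rho) / s2;
    return Q;
  }
  for (int t = 0; t < T; ++t)
    Q(t, t) = (t == 0 || t == T - 1) ? 1.0 / s2 : (1.0 + rho * rho) / s2;
  for (int t = 0; t < T - 1; ++t) {
    Q(t, t + 1) = -rho / s2;
    Q(t + 1, t) = -rho / s2;
  }
  return Q;
}

// draw from N(A^{-1} b, A^{-1}) via Cholesky of the precision A
static arma::vec mvn_precision(const arma::mat& A, const arma::vec& b) {
  arma::mat R = arma::chol(A);  // A = R' R, R upper
  arma::vec mu = arma::solve(arma::trimatu(R),
                             arma::solve(arma::trimatl(R.t()), b));
  arma::vec zv(b.n_elem);
  for (arma::uword i = 0; i < b.n_elem; ++i) zv[i] = norm_rand();
  return mu + arma::solve(arma::trimatu(R), zv);
}

// [[Rcpp::export]]
List bhm_gibbs_cpp(const arma::mat& X, const arma::vec& y,
                   const arma::uvec& area, const arma::uvec& round,
                   int K, int T,
                   const arma::vec& beta_mean, const arma::vec& beta_sd,
                   double sigma_scale, double rho_a, double rho_b,
                   int n_warmup, int n_keep, int thin,
                   arma::vec beta, arma::mat u, double rho, double sigma) {
  int n = X.n_rows, p = X.n_cols;
  arma::vec kappa = y - 0.5;
  arma::vec prior_prec = 1.0 / arma::square(beta_sd);
  arma::vec prior_b = beta_mean % prior_prec;

  arma::mat beta_out(n_keep, p);
  arma::mat u_out(n_keep, K * T);
  arma::vec rho_out(n_keep), sigma_out(n_keep);

  double ls_rho = std::log(0.3), ls_sigma = std::log(0.3);  // proposal scales
  int acc_rho = 0, acc_sigma = 0, try_rho = 0, try_sigma = 0;
  int acc_rho_post = 0, acc_sigma_post = 0, n_post = 0;

  arma::vec omega(n), eta(n), uvecn(n);
  int total = n_warmup + n_keep * thin;

  for (int it = 0; it < total; ++it) {
    // linear predictor and PG draws
    eta = X * beta;
    for (int i = 0; i < n; ++i) {
      uvecn[i] = u(area[i], round[i]);
      omega[i] = rpg1(eta[i] + uvecn[i]);
    }

    // beta | omega, u
    arma::mat Xw = X.each_col() % omega;
    arma::mat A = X.t() * Xw;
    A.diag() += prior_prec;
    arma::vec b = X.t() * (kappa - omega % uvecn) + prior_b;
    beta = mvn_precision(A, b);
    eta = X * beta;

    // u | omega, beta, rho, sigma : independent T-dim Gaussians per area
    arma::mat cw(K, T, arma::fill::zeros), cb(K, T, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      cw(area[i], round[i]) += omega[i];
      cb(area[i], round[i]) += kappa[i] - omega[i] * eta[i];
    }
    arma::mat Q = ar1_precision(T, rho, sigma);
    for (int k = 0; k < K; ++k) {
      arma::mat Ak = Q;
      Ak.diag() += cw.row(k).t();
      u.row(k) = mvn_precision(Ak, cb.row(k).t()).t();
    }

    // rho | u, sigma : RW Metropolis on atanh(rho); Beta(a,b) prior on
    // (rho+1)/2; Jacobian log(1 - rho^2)
    {
      ++try_rho;
      double et = std::atanh(rho);
      double etp = et + std::exp(ls_rho) * norm_rand();
      double rp = std::tanh(etp);
      double lcur = ar1_logdens(u, rho, sigma) +
                    (rho_a - 1.0) * std::log1p(rho) +
                    (rho_b - 1.0) * std::log1p(-rho) +
                    std::log1p(-rho * rho);
      double lprop = ar1_logdens(u, rp, sigma) +
                     (rho_a - 1.0) * std::log1p(rp) +
                     (rho_b - 1.0) * std::log1p(-rp) +
                     std::log1p(-rp * rp);
      if (std::log(unif_rand()) < lprop - lcur) {
        rho = rp;
        ++acc_rho;
        if (it >= n_warmup) ++acc_rho_post;
      }
      if (it < n_warmup && try_rho % 50 == 0)
        ls_rho += (acc_rho / 50.0 > 0.44 ? 0.1 : -0.1), acc_rho = 0;
    }

    // sigma | u, rho : RW Metropolis on log(sigma); Half-Normal(scale) prior
    {
      ++try_sigma;
      double lsig = std::log(sigma);
      double lsp = lsig + std::exp(ls_sigma) * norm_rand();
      double sp = std::exp(lsp);
      double hs = 2.0 * sigma_scale * sigma_scale;
      double lcur = ar1_logdens(u, rho, sigma) - sigma * sigma / hs + lsig;
      double lprop = ar1_logdens(u, rho, sp) - sp * sp / hs + lsp;
      if (std::log(unif_rand()) < lprop - lcur) {
        sigma = sp;
        ++acc_sigma;
        if (it >= n_warmup) ++acc_sigma_post;
      }
      if (it < n_warmup && try_sigma % 50 == 0)
        ls_sigma += (acc_sigma / 50.0 > 0.44 ? 0.1 : -0.1), acc_sigma = 0;
    }

    if (it >= n_warmup) ++n_post;
    if (it >= n_warmup && (it - n_warmup) % thin == 0) {
      int s = (it - n_warmup) / thin;
      beta_out.row(s) = beta.t();
      u_out.row(s) = arma::vectorise(u).t();  // column-major: area fastest
      rho_out[s] = rho;
      sigma_out[s] = sigma;
    }
  }

  return List::create(_["beta"] = beta_out, _["u"] = u_out,
                      _["rho"] = rho_out, _["sigma"] = sigma_out,
                      _["accept_rho"] = double(acc_rho_post) / std::max(1, n_post),
                      _["accept_sigma"] =
                          double(acc_sigma_post) / std::max(1, n_post));
}
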