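// Generalized inverse Gaussian variate generation and the Gibbs sweep for the
// log-normal mixed model.  The GIG sampler follows the three-region scheme of
// Hormann & Leydold (2014): mode-shifted ratio-of-uniforms for large shape or
// concentration, plain ratio-of-uniforms in the central region, and a
// two-piece hat (power hat near 0, exponential tail) for the almost-singular
// region lambda < 1, small omega.  Boundary cases delta = 0 (Gamma) and
// gamma = 0 (inverse gamma) dispatch to the standard generators so a single
// code path serves both GIG and inverse-gamma priors.  All draws consume R's
// RNG stream, so set.seed() on the R side gives bitwise reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// log of the two-parameter quasi-density y^(lambda-1) exp(-omega/2 (y + 1/y))
static inline double gig_lqd(double y, double lambda, double omega) {
  return (lambda - 1.0) * std::log(y) - 0.5 * omega * (y + 1.0 / y);
}

static inline double gig_mode(double lambda, double omega) {
  if (lambda >= 1.0)
    return (std::sqrt((lambda - 1.0) * (lambda - 1.0) + omega * omega) +
            (lambda - 1.0)) / omega;
  // reciprocal form is accurate for lambda < 1
  return omega / (std::sqrt((1.0 - lambda) * (1.0 - lambda) + omega * omega) +
                  (1.0 - lambda));
}

// plain ratio-of-uniforms, quasi-density normalised at the mode; valid for any
// (lambda, omega), efficient in the central region
static double rgig_rou_noshift(double lambda, double omega) {
  const double xm = gig_mode(lambda, omega);
  const double lgm = gig_lqd(xm, lambda, omega);
  // maximiser of x * sqrt(g(x)), i.e. mode of the quasi-density with lambda+2
  const double xp = ((lambda + 1.0) +
                     std::sqrt((lambda + 1.0) * (lambda + 1.0) + omega * omega)) / omega;
  const double vmax = xp * std::exp(0.5 * (gig_lqd(xp, lambda, omega) - lgm));
  double u, x;
  do {
    u = unif_rand();
    x = vmax * unif_rand() / u;
  } while (2.0 * std::log(u) > gig_lqd(x, lambda, omega) - lgm);
  return x;
}

// mode-shifted ratio-of-uniforms; u-range endpoints solve the cubic that makes
// (x - xm)^2 g(x) stationary
static double rgig_rou_shift(double lambda, double omega) {
  const double xm = gig_mode(lambda, omega);
  const double lgm = gig_lqd(xm, lambda, omega);
  const double a = -(2.0 * (lambda + 1.0) / omega + xm);
  const double b = 2.0 * (lambda - 1.0) * xm / omega - 1.0;
  const double p = b - a * a / 3.0;
  const double q = 2.0 * a * a * a / 27.0 - a * b / 3.0 + xm;
  // three real roots (trigonometric form); largest and middle bracket the mode
  const double fi = std::acos(-q / (2.0 * std::sqrt(-(p * p * p) / 27.0)));
  const double fak = 2.0 * std::sqrt(-p / 3.0);
  const double y1 = fak * std::cos(fi / 3.0) - a / 3.0;
  const double y2 = fak * std::cos(fi / 3.0 + 4.0 * M_PI / 3.0) - a / 3.0;
  if (y2 <= 0.0)  // outside this branch's validity region; fall back
    return rgig_rou_noshift(lambda, omega);
  const double uplus  = (y1 - xm) * std::exp(0.5 * (gig_lqd(y1, lambda, omega) - lgm));
  const double uminus = (y2 - xm) * std::exp(0.5 * (gig_lqd(y2, lambda, omega) - lgm));
  double u, v, x;
  do {
    u = uminus + unif_rand() * (uplus - uminus);
    v = unif_rand();
    x = u / v + xm;
  } while (x <= 0.0 || 2.0 * std::log(v) > gig_lqd(x, lambda, omega) - lgm);
  return x;
}

// two-piece hat for 0 < lambda < 1, small omega: power hat k0 x^(lambda-1) on
// (0, x0] (using exp(-omega/2 (x + 1/x)) <= exp(-omega)), exponential hat on
// (x0, Inf) (using x^(lambda-1) <= x0^(lambda-1))
static double rgig_two_piece(double lambda, double omega) {
  const double x0 = omega / (1.0 - lambda);
  const double k0 = std::exp(-omega);
  const double lk1 = (lambda - 1.0) * std::log(x0);
  const double A1 = k0 * std::pow(x0, lambda) / lambda;
  const double A2 = std::exp(lk1 - 0.5 * omega * x0) * 2.0 / omega;
  double x, lhat;
  do {
    if (unif_rand() * (A1 + A2) < A1) {
      x = x0 * std::pow(unif_rand(), 1.0 / lambda);
      lhat = std::log(k0) + (lambda - 1.0) * std::log(x);
    } else {
      x = x0 - 2.0 / omega * std::log(unif_rand());
      lhat = lk1 - 0.5 * omega * x;
    }
  } while (std::log(unif_rand()) > gig_lqd(x, lambda, omega) - lhat);
  return x;
}

// standardised GIG(lambda, omega), lambda >= 0, omega > 0
static double rgig_std(double lambda, double omega) {
  if (lambda > 2.0 || omega > 3.0)
    return rgig_rou_shift(lambda, omega);
  if (lambda >= 1.0 - 2.25 * omega * omega || omega > 0.2)
    return rgig_rou_noshift(lambda, omega);
  if (lambda > 0.0)
    return rgig_two_piece(lambda, omega);
  return rgig_rou_noshift(lambda, omega);  // lambda == 0, tiny omega
}

// one draw from GIG(lambda, delta, gamma) in the (lambda, delta, gamma)
// parameterisation; boundaries handled exactly
static double rgig_one(double lambda, double delta, double gamma) {
  if (delta == 0.0)  // Gamma(lambda, rate = gamma^2/2)
    return R::rgamma(lambda, 2.0 / (gamma * gamma));
  if (gamma == 0.0)  // inverse gamma(-lambda, scale par delta^2/2)
    return 1.0 / R::rgamma(-lambda, 2.0 / (delta * delta));
  const double omega = delta * gamma;
  double y = rgig_std(std::fabs(lambda), omega);
  if (lambda < 0.0) y = 1.0 / y;  // duality 1/V ~ GIG(-lambda, gamma, delta)
  return (delta / gamma) * y;
}

// [[Rcpp::export]]
NumericVector rgig_cpp(int n, double lambda, double delta, double gamma) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rgig_one(lambda, delta, gamma);
  return out;
}

// Full Gibbs sweep for w = X beta + Z u + eps with GIG priors on the variance
// components and a flat improper prior on beta.  Update order per sweep:
// sigma2 -> tau2_s -> u -> beta.  msizes gives the random-effect block sizes.
// fix_variances freezes sigma2/tau2 at their initial values (used for the
// closed-form conditional-posterior cross-checks).
// [[Rcpp::export]]
List gibbs_lmm_cpp(const arma::vec& w, const arma::mat& X, const arma::mat& Z,
                   const arma::ivec& msizes,
                   double lam_s, double del_s, double gam_s,
                   const arma::vec& lam_t, const arma::vec& del_t,
                   const arma::vec& gam_t,
                   int n_iter, int burn_in,
                   arma::vec beta, arma::vec u, double sig2, arma::vec tau2,
                   bool fix_variances) {
  const int n = (int) w.n_elem, p = (int) X.n_cols, m = (int) Z.n_cols;
  const int q = (int) msizes.n_elem;
  const int keep = n_iter - burn_in;

  const arma::mat XtX = X.t() * X;
  const arma::mat Rx = arma::chol(XtX);        // upper: XtX = Rx' Rx
  const arma::mat ZtZ = Z.t() * Z;
  const arma::mat Zt = Z.t();

  arma::mat beta_out(keep, p), u_out(keep, m), tau2_out(keep, q);
  arma::vec sig2_out(keep);

  arma::vec zdraw(m), zb(p);
  int row = 0;
  for (int it = 1; it <= n_iter; ++it) {
    if (!fix_variances) {
      const arma::vec resid = w - X * beta - Z * u;
      const double rss = arma::dot(resid, resid);
      sig2 = rgig_one(lam_s - 0.5 * n, std::sqrt(rss + del_s * del_s), gam_s);
      int pos = 0;
      for (int s = 0; s < q; ++s) {
        const int ms = msizes[s];
        const double ss = arma::dot(u.subvec(pos, pos + ms - 1),
                                    u.subvec(pos, pos + ms - 1));
        tau2[s] = rgig_one(lam_t[s] - 0.5 * ms,
                           std::sqrt(ss + del_t[s] * del_t[s]), gam_t[s]);
        pos += ms;
      }
    }
    // u | . ~ N(A^{-1} Z'(w - X beta), sig2 A^{-1}), A = Z'Z + sig2 D^{-1}
    arma::mat A = ZtZ;
    {
      int pos = 0;
      for (int s = 0; s < q; ++s) {
        const int ms = msizes[s];
        for (int j = pos; j < pos + ms; ++j) A(j, j) += sig2 / tau2[s];
        pos += ms;
      }
    }
    arma::mat Ru;
    if (!arma::chol(Ru, A))
      stop("Cholesky factorisation of the random-effect precision failed");
    const arma::vec bu = Zt * (w - X * beta);
    const arma::vec mu_u = arma::solve(arma::trimatu(Ru),
                           arma::solve(arma::trimatl(Ru.t()), bu));
    for (int j = 0; j < m; ++j) zdraw[j] = norm_rand();
    u = mu_u + std::sqrt(sig2) * arma::solve(arma::trimatu(Ru), zdraw);

    // beta | . ~ N((X'X)^{-1} X'(w - Z u), sig2 (X'X)^{-1})
    const arma::vec bb = X.t() * (w - Z * u);
    const arma::vec mu_b = arma::solve(arma::trimatu(Rx),
                           arma::solve(arma::trimatl(Rx.t()), bb));
    for (int j = 0; j < p; ++j) zb[j] = norm_rand();
    beta = mu_b + std::sqrt(sig2) * arma::solve(arma::trimatu(Rx), zb);

    if (it > burn_in) {
      beta_out.row(row) = beta.t();
      u_out.row(row) = u.t();
      sig2_out[row] = sig2;
      tau2_out.row(row) = tau2.t();
      ++row;
    }
  }
  return List::create(_["beta"] = beta_out, _["u"] = u_out,
                      _["sigma2"] = sig2_out, _["tau2"] = tau2_out);
}
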