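// Monte Carlo kernel for the stochastic complexity integral
//   c_M = log \int dg sqrt(det J(g)),
// under the substitution g_mu = atanh(sin theta_mu), theta uniform on
// (-pi/2, pi/2)^m, whose Jacobian is 1 / prod_mu cos(theta_mu).
// For each theta sample the exact Fisher matrix J(g) is computed by full
// state enumeration (Phi holds phi_mu(s) for all 2^n states), and the
// integrand sqrt(det J) * Jacobian is accumulated.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".jeffreys_integrand_mean")]]
double jeffreys_integrand_mean(const arma::mat& Phi, const arma::mat& Theta) {
  const arma::uword m = Phi.n_cols;
  const arma::uword S = Theta.n_cols;
  if (Theta.n_rows != m)
    stop("Theta must have one row per operator");
  if (m == 0)
    stop("empty model has no parameters to integrate over");

  double acc = 0.0;
  arma::vec g(m), p, mu, eval;
  arma::mat J(m, m);

  for (arma::uword s = 0; s < S; ++s) {
    double log_jac = 0.0;  // -sum log cos(theta)
    for (arma::uword j = 0; j < m; ++j) {
      const double th = Theta(j, s);
      g[j] = std::atanh(std::sin(th));
      log_jac -= std::log(std::cos(th));
    }
    arma::vec e = Phi * g;
    e -= e.max();
    p = arma::exp(e);
    p /= arma::accu(p);
    mu = Phi.t() * p;
    J = Phi.t() * (Phi.each_col() % p) - mu * mu.t();
    J = arma::symmatu(0.5 * (J + J.t()));
    if (!arma::eig_sym(eval, J))
      stop("eigendecomposition of the Fisher matrix failed");
    double half_logdet = 0.0;
    bool singular = false;
    for (arma::uword j = 0; j < m; ++j) {
      double ev = eval[j];
      if (ev < -1e-10)
        stop("Fisher matrix has a negative eigenvalue (%g) at sample %d",
             ev, (int)(s + 1));
      if (ev <= 0.0) { singular = true; break; }
      half_logdet += 0.5 * std::log(ev);
    }
    // sqrt(det) of a singular J is 0: correct for the volume element
    const double val = singular ? 0.0 : std::exp(half_logdet + log_jac);
    if (!std::isfinite(val))
      stop("non-finite integrand at sample %d (theta_1 = %g)",
           (int)(s + 1), Theta(0, s));
    acc += val;
  }
  return acc / (double)S;
}
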