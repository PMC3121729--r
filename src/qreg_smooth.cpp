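#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Smoothed check loss: the kink of rho_tau(r) = r * (tau - I(r < 0)) is
// replaced by a quadratic on (-gamma*(1-tau), gamma*tau) so the objective is
// C1 and piecewise quadratic:
//   r >=  gamma*tau        : tau*r - gamma*tau^2/2
//   -gamma*(1-tau) < r < . : r^2 / (2*gamma)
//   r <= -gamma*(1-tau)    : (tau-1)*r - gamma*(1-tau)^2/2
// Value and derivative are continuous; as gamma -> 0 it converges to rho_tau.

static double smooth_obj(const vec& r, double tau, double gamma) {
  double s = 0.0, hi = gamma * tau, lo = -gamma * (1.0 - tau);
  for (uword i = 0; i < r.n_elem; ++i) {
    double ri = r(i);
    if (ri >= hi)      s += tau * ri - 0.5 * gamma * tau * tau;
    else if (ri <= lo) s += (tau - 1.0) * ri - 0.5 * gamma * (1.0 - tau) * (1.0 - tau);
    else               s += ri * ri / (2.0 * gamma);
  }
  return s;
}

// [[Rcpp::export(name = ".qreg_check_objective_cpp")]]
double qreg_check_objective_cpp(const arma::vec& r, double tau) {
  double s = 0.0;
  for (uword i = 0; i < r.n_elem; ++i)
    s += r(i) * (tau - (r(i) < 0.0 ? 1.0 : 0.0));
  return s;
}

// Damped Newton minimization of the smoothed objective over a geometric
// gamma-reduction schedule. Returns beta plus convergence metadata.
// [[Rcpp::export(name = ".qreg_smooth_fit_cpp")]]
Rcpp::List qreg_smooth_fit_cpp(const arma::mat& X, const arma::vec& y,
                               double tau, arma::vec beta0,
                               double gamma0, double shrink,
                               double gamma_min, double tol, int max_iter) {
  const uword n = X.n_rows, p = X.n_cols;
  vec beta = beta0;
  int total_iter = 0;
  bool converged = true;
  double gamma = gamma0;
  if (gamma <= gamma_min) gamma = gamma_min * 10.0;

  while (true) {
    vec r = y - X * beta;
    double f = smooth_obj(r, tau, gamma);
    for (int it = 0; it < max_iter; ++it) {
      ++total_iter;
      double hi = gamma * tau, lo = -gamma * (1.0 - tau);
      vec psi(n);
      uvec mid(n);
      uword nmid = 0;
      for (uword i = 0; i < n; ++i) {
        double ri = r(i);
        if (ri >= hi)      { psi(i) = tau; }
        else if (ri <= lo) { psi(i) = tau - 1.0; }
        else               { psi(i) = ri / gamma; mid(nmid++) = i; }
      }
      vec g = -(X.t() * psi);            // gradient of the smoothed objective
      double gnorm = norm(g, "inf");
      if (gnorm < tol * (1.0 + std::abs(f))) break;

      mat H(p, p, fill::zeros);
      if (nmid > 0) {
        mat Xm = X.rows(mid.head(nmid));
        H = (Xm.t() * Xm) / gamma;
      }
      // Guard against a rank-deficient curvature block (fewer than p interior
      // residuals): ridge regularization keeps the step a descent direction.
      double ridge = 1e-8 * (1.0 + trace(H) / p);
      H.diag() += ridge;
      vec step;
      bool ok = solve(step, H, -g, solve_opts::no_approx + solve_opts::likely_sympd);
      if (!ok) {
        H.diag() += 1e-2 * (1.0 + trace(H) / p);
        if (!solve(step, H, -g, solve_opts::no_approx)) { converged = false; break; }
      }
      // backtracking line search on the smoothed objective
      double t = 1.0, fnew = f;
      vec bnew = beta;
      bool improved = false;
      for (int ls = 0; ls < 40; ++ls) {
        bnew = beta + t * step;
        fnew = smooth_obj(y - X * bnew, tau, gamma);
        if (fnew <= f - 1e-12 * std::abs(f)) { improved = true; break; }
        t *= 0.5;
      }
      if (!improved) break;              // stationary for this gamma
      beta = bnew;
      r = y - X * beta;
      double df = f - fnew;
      f = fnew;
      if (df < tol * (1.0 + std::abs(f)) && norm(t * step, "inf") < tol) break;
    }
    if (gamma <= gamma_min) break;
    gamma *= shrink;
    if (gamma < gamma_min) gamma = gamma_min;
  }

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("iterations") = total_iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("gamma_final") = gamma);
}
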