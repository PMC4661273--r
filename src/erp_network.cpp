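// Fixed-step RK4 integration of the coupled damped-oscillator source
// network. Kept deliberately simple: a small dense state, an analytic
// Gaussian-bump input, and bit-deterministic fixed-step integration.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// dx/dt = v
// dv/dt = kappa^2 (W tanh(x) + g u(t) - x) - 2 kappa v
static inline void deriv(const vec& x, const vec& v, const mat& W,
                         const vec& g, double u, double kappa,
                         vec& dx, vec& dv) {
  dx = v;
  dv = kappa * kappa * (W * tanh(x) + g * u - x) - 2.0 * kappa * v;
}

// [[Rcpp::export(name = ".erpIntegrate")]]
arma::mat erp_integrate(const arma::mat& W, const arma::vec& g,
                        double kappa, double muU, double sigmaU,
                        const arma::mat& G, const arma::vec& gains,
                        int nBins, double binS, int nSub) {
  const int ns = W.n_rows;
  const int nch = G.n_rows;
  const double dt = binS / nSub;
  vec x(ns, fill::zeros), v(ns, fill::zeros);
  vec k1x(ns), k1v(ns), k2x(ns), k2v(ns), k3x(ns), k3v(ns), k4x(ns), k4v(ns);
  vec xt(ns), vt(ns);
  mat out(nch, nBins);
  double t = 0.0;
  auto input = [&](double tt) {
    double z = (tt - muU) / sigmaU;
    return std::exp(-0.5 * z * z);
  };
  for (int b = 0; b < nBins; ++b) {
    for (int s = 0; s < nSub; ++s) {
      double u1 = input(t), u2 = input(t + dt / 2.0), u3 = input(t + dt);
      deriv(x, v, W, g, u1, kappa, k1x, k1v);
      xt = x + 0.5 * dt * k1x; vt = v + 0.5 * dt * k1v;
      deriv(xt, vt, W, g, u2, kappa, k2x, k2v);
      xt = x + 0.5 * dt * k2x; vt = v + 0.5 * dt * k2v;
      deriv(xt, vt, W, g, u2, kappa, k3x, k3v);
      xt = x + dt * k3x; vt = v + dt * k3v;
      deriv(xt, vt, W, g, u3, kappa, k4x, k4v);
      x += dt / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
      v += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
      t += dt;
    }
    if (!x.is_finite() || abs(x).max() > 1e6)
      Rcpp::stop("diverged trajectory during network integration");
    out.col(b) = gains % (G * x);
  }
  return out;
}
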