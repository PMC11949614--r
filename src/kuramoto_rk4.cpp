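#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Fixed-step RK4 integration of the Kuramoto phase equations
//   dtheta_a/dt = omega_a + g * sum_b W(b, a) * sin(theta_b - theta_a)
// with row = source, column = target (W(b, a) couples oscillator b into a).
// The coupling sum is evaluated through the expansion
//   sum_b W(b,a) sin(theta_b - theta_a)
//     = cos(theta_a) * (W' sin(theta))_a - sin(theta_a) * (W' cos(theta))_a
// so each derivative costs two matrix-vector products.
//
// Phases are sampled every `stride` steps once t >= transient; raw (unwrapped)
// phases are returned since downstream statistics use exp(i*theta) and
// sin(theta) only.
// [[Rcpp::export]]
Rcpp::List kuramoto_rk4_cpp(const arma::mat& W,
                            const arma::vec& omega,
                            const arma::vec& theta0,
                            double g,
                            double dt,
                            double duration,
                            double transient,
                            double sample_dt) {
  const arma::mat Wt = W.t();
  const arma::uword n = omega.n_elem;

  auto deriv = [&](const arma::vec& th) -> arma::vec {
    arma::vec s = arma::sin(th), c = arma::cos(th);
    return omega + g * (c % (Wt * s) - s % (Wt * c));
  };

  const int n_steps    = (int) std::llround(duration / dt);
  const int stride     = std::max(1, (int) std::llround(sample_dt / dt));
  const int first_keep = (int) std::llround(transient / dt);

  const int n_samples = (n_steps - first_keep) / stride + 1;
  arma::mat samples(n_samples, n);
  arma::vec times(n_samples);

  arma::vec th = theta0;
  double max_rate = 0.0;
  int isamp = 0;

  for (int k = 0; k <= n_steps; ++k) {
    if (k >= first_keep && ((k - first_keep) % stride == 0) && isamp < n_samples) {
      samples.row(isamp) = th.t();
      times(isamp) = k * dt;
      ++isamp;
    }
    if (k == n_steps) break;
    arma::vec k1 = deriv(th);
    arma::vec k2 = deriv(th + 0.5 * dt * k1);
    arma::vec k3 = deriv(th + 0.5 * dt * k2);
    arma::vec k4 = deriv(th + dt * k3);
    double r = arma::abs(k1).max();
    if (r > max_rate) max_rate = r;
    th += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }

  return Rcpp::List::create(Rcpp::Named("theta")    = samples,
                            Rcpp::Named("times")    = times,
                            Rcpp::Named("max_rate") = max_rate);
}
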