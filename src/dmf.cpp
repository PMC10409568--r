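// Core numerical loops: Euler-Maruyama integration of the two-population
// reduced mean-field network, and the Balloon-Windkessel haemodynamic ODEs.
// Kept in C++ because the model runs at dt = 1 ms for minutes of biological
// time; everything scientific (parameters, FIC logic, statistics) lives in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// f-I curve (aI - b) / (1 - exp(-d (aI - b))), continuous at 0 with limit 1/d
static inline double phi(double x, double d) {
  if (std::fabs(d * x) < 1e-9) return 1.0 / d + x / 2.0;
  return x / (1.0 - std::exp(-d * x));
}

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z(i) = ::norm_rand();
  return z;
}

// [[Rcpp::export(name = ".dmf_simulate_cpp")]]
List dmf_simulate_cpp(const arma::mat& C, const arma::vec& J,
                      const List& par,
                      arma::vec S_E, arma::vec S_I,
                      int n_steps, int transient_steps,
                      int record_every) {
  const int n = C.n_rows;
  const double w_E = par["w_E"], w_I = par["w_I"], I_0 = par["I_0"];
  const double w_plus = par["w_plus"], J_N = par["J_N"], w_II = par["w_II"];
  const double G = par["G"];
  const double a_E = par["a_E"], b_E = par["b_E"], d_E = par["d_E"];
  const double a_I = par["a_I"], b_I = par["b_I"], d_I = par["d_I"];
  const double tau_E = par["tau_E"], tau_I = par["tau_I"];
  const double gamma = par["gamma"], sigma = par["sigma"], dt = par["dt"];
  const double sqdt = std::sqrt(dt);

  arma::vec sum_rE(n, arma::fill::zeros), sum_rI(n, arma::fill::zeros);
  arma::vec sum_IE(n, arma::fill::zeros);
  long n_avg = 0;

  int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  arma::mat rec;
  if (n_rec > 0) rec.set_size(n, n_rec);
  int i_rec = 0;

  RNGScope scope;
  arma::vec I_E(n), I_I(n), r_E(n), r_I(n);
  for (int t = 0; t < n_steps; ++t) {
    I_E = w_E * I_0 + w_plus * J_N * S_E + G * J_N * (C * S_E) - J % S_I;
    I_I = w_I * I_0 + J_N * S_E - w_II * S_I;
    for (int i = 0; i < n; ++i) {
      r_E(i) = phi(a_E * I_E(i) - b_E, d_E);
      r_I(i) = phi(a_I * I_I(i) - b_I, d_I);
    }
    if (t >= transient_steps) {
      sum_rE += r_E; sum_rI += r_I; sum_IE += I_E; ++n_avg;
    }
    // rates are in Hz, time in ms
    S_E += dt * (-S_E / tau_E + (1.0 - S_E) % (gamma / 1000.0 * r_E));
    S_I += dt * (-S_I / tau_I + r_I / 1000.0);
    if (sigma > 0) {
      S_E += sigma * sqdt * rnorm_vec(n);
      S_I += sigma * sqdt * rnorm_vec(n);
    }
    S_E = arma::clamp(S_E, 0.0, 1.0);
    S_I = arma::clamp(S_I, 0.0, 1.0);
    if (!S_E.is_finite() || !S_I.is_finite())
      stop("non-finite gating state at step %d", t + 1);
    if (record_every > 0 && (t + 1) % record_every == 0 && i_rec < n_rec)
      rec.col(i_rec++) = S_E;
  }

  double denom = (n_avg > 0) ? (double)n_avg : 1.0;
  return List::create(
    _["r_E"] = sum_rE / denom, _["r_I"] = sum_rI / denom,
    _["I_E"] = sum_IE / denom,
    _["S_E"] = S_E, _["S_I"] = S_I,
    _["activity"] = rec);
}

// Balloon-Windkessel haemodynamics driven by synaptic activity z(t).
// States per region: vasodilatory signal s, blood flow f, volume v,
// deoxyhaemoglobin q. Euler at the sampling interval of `activity`.
// [[Rcpp::export(name = ".balloon_bold_cpp")]]
arma::mat balloon_bold_cpp(const arma::mat& activity, double dt_s,
                           double kappa, double gamma_h, double tau,
                           double alpha, double rho, double V0) {
  const int n = activity.n_rows, T = activity.n_cols;
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  arma::mat bold(n, T);
  for (int i = 0; i < n; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    for (int t = 0; t < T; ++t) {
      double z = activity(i, t);
      double ds = z - kappa * s - gamma_h * (f - 1.0);
      double df = s;
      double dv = (f - std::pow(v, 1.0 / alpha)) / tau;
      double Ef = 1.0 - std::pow(1.0 - rho, 1.0 / f);
      double dq = (f * Ef / rho - std::pow(v, 1.0 / alpha) * q / v) / tau;
      s += dt_s * ds; f += dt_s * df; v += dt_s * dv; q += dt_s * dq;
      if (f < 1e-6) f = 1e-6;
      if (v < 1e-6) v = 1e-6;
      bold(i, t) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    }
    if (!bold.row(i).is_finite())
      stop("non-finite BOLD signal for region %d", i + 1);
  }
  return bold;
}
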