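// Dynamic mean-field (reduced excitatory-inhibitory) whole-brain model and
// Balloon-Windkessel haemodynamics. Euler-Maruyama integration; all noise is
// drawn from R's RNG so set.seed() in R gives bit-reproducible runs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double transfer(double I, double a, double b, double d) {
  double x = a * I - b;
  // transfer r(I) = x / (1 - exp(-d x)); limit x -> 0 is 1/d
  if (std::fabs(x) < 1e-9) return 1.0 / d;
  return x / (1.0 - std::exp(-d * x));
}

// [[Rcpp::export(name = ".dmf_integrate_cpp")]]
List dmf_integrate_cpp(const arma::mat& C, double G, const arma::vec& J,
                       List pars, double duration_ms, double dt_ms,
                       double record_dt_ms, double discard_ms, double sigma) {
  const int n = C.n_rows;
  const double I0      = as<double>(pars["I0"]);
  const double w_E     = as<double>(pars["w_E"]);
  const double w_I     = as<double>(pars["w_I"]);
  const double w_plus  = as<double>(pars["w_plus"]);
  const double J_NMDA  = as<double>(pars["J_NMDA"]);
  const double a_E     = as<double>(pars["a_E"]);
  const double b_E     = as<double>(pars["b_E"]);
  const double d_E     = as<double>(pars["d_E"]);
  const double a_I     = as<double>(pars["a_I"]);
  const double b_I     = as<double>(pars["b_I"]);
  const double d_I     = as<double>(pars["d_I"]);
  const double tau_E   = as<double>(pars["tau_E"]);   // ms
  const double tau_I   = as<double>(pars["tau_I"]);   // ms
  const double gamma_E = as<double>(pars["gamma"]);   // dimensionless (0.641)

  const int n_steps = (int) std::llround(duration_ms / dt_ms);
  const int rec_every = std::max(1, (int) std::llround(record_dt_ms / dt_ms));
  const int discard_steps = (int) std::llround(discard_ms / dt_ms);
  const int n_rec = (n_steps - discard_steps) / rec_every;
  if (n_rec <= 0) stop("duration too short for the requested discard/recording");

  arma::vec S_E(n, arma::fill::value(0.1));
  arma::vec S_I(n, arma::fill::value(0.1));
  arma::vec I_E(n), I_I(n), r_E(n), r_I(n);
  arma::mat S_rec(n, n_rec, arma::fill::zeros);
  arma::vec rate_sum(n, arma::fill::zeros);
  arma::vec IE_sum(n, arma::fill::zeros);
  arma::vec SI_sum(n, arma::fill::zeros);
  long long n_acc = 0;
  const double sqdt = std::sqrt(dt_ms);
  bool ok = true;
  int rec_idx = 0;

  RNGScope scope;
  for (int step = 0; step < n_steps; ++step) {
    arma::vec coupling = C * S_E;
    for (int i = 0; i < n; ++i) {
      I_E[i] = w_E * I0 + w_plus * J_NMDA * S_E[i] + G * J_NMDA * coupling[i]
               - J[i] * S_I[i];
      I_I[i] = w_I * I0 + J_NMDA * S_E[i] - S_I[i];
      r_E[i] = transfer(I_E[i], a_E, b_E, d_E);
      r_I[i] = transfer(I_I[i], a_I, b_I, d_I);
    }
    for (int i = 0; i < n; ++i) {
      double dSE = -S_E[i] / tau_E + (1.0 - S_E[i]) * gamma_E * r_E[i] / 1000.0;
      double dSI = -S_I[i] / tau_I + r_I[i] / 1000.0;
      double nE = (sigma > 0.0) ? sigma * norm_rand() : 0.0;
      double nI = (sigma > 0.0) ? sigma * norm_rand() : 0.0;
      S_E[i] += dt_ms * dSE + sqdt * nE;
      S_I[i] += dt_ms * dSI + sqdt * nI;
      if (S_E[i] < 0.0) S_E[i] = 0.0; else if (S_E[i] > 1.0) S_E[i] = 1.0;
      if (S_I[i] < 0.0) S_I[i] = 0.0; else if (S_I[i] > 1.0) S_I[i] = 1.0;
    }
    if (!S_E.is_finite() || !S_I.is_finite()) { ok = false; break; }
    if (step >= discard_steps) {
      rate_sum += r_E;
      IE_sum += I_E;
      SI_sum += S_I;
      ++n_acc;
      if ((step - discard_steps) % rec_every == 0 && rec_idx < n_rec) {
        S_rec.col(rec_idx++) = S_E;
      }
    }
  }
  if (n_acc == 0) n_acc = 1;
  return List::create(
    _["S_E"] = S_rec.cols(0, std::max(0, rec_idx - 1)),
    _["rate_mean"] = rate_sum / (double) n_acc,
    _["IE_mean"] = IE_sum / (double) n_acc,
    _["SI_mean"] = SI_sum / (double) n_acc,
    _["record_dt_ms"] = rec_every * dt_ms,
    _["ok"] = ok);
}

// Balloon-Windkessel haemodynamics: four states per region (vasodilatory
// signal s, inflow f, venous volume v, deoxyhaemoglobin q), driven by the
// excitatory synaptic gating trace. Input columns are spaced dt_s seconds;
// output is BOLD sampled every tr_s seconds.
// [[Rcpp::export(name = ".balloon_windkessel_cpp")]]
arma::mat balloon_windkessel_cpp(const arma::mat& Z, double dt_s, double tr_s,
                                 double kappa, double gamma, double tau,
                                 double alpha, double rho, double V0) {
  const int n = Z.n_rows;
  const int n_t = Z.n_cols;
  if (!Z.is_finite()) stop("non-finite input to balloon_windkessel");
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  const int out_every = std::max(1, (int) std::llround(tr_s / dt_s));
  const int n_out = n_t / out_every;
  arma::mat bold(n, n_out, arma::fill::zeros);
  arma::vec s(n, arma::fill::zeros), f(n, arma::fill::ones),
            v(n, arma::fill::ones), q(n, arma::fill::ones);
  int oi = 0;
  for (int t = 0; t < n_t; ++t) {
    for (int i = 0; i < n; ++i) {
      double z = Z(i, t);
      double fv = std::pow(v[i], 1.0 / alpha);
      double E = 1.0 - std::pow(1.0 - rho, 1.0 / f[i]);
      double ds = z - kappa * s[i] - gamma * (f[i] - 1.0);
      double df = s[i];
      double dv = (f[i] - fv) / tau;
      double dq = (f[i] * E / rho - fv * q[i] / v[i]) / tau;
      s[i] += dt_s * ds;
      f[i] += dt_s * df;
      v[i] += dt_s * dv;
      q[i] += dt_s * dq;
      if (f[i] < 1e-4) f[i] = 1e-4;
      if (v[i] < 1e-4) v[i] = 1e-4;
      if (q[i] < 1e-4) q[i] = 1e-4;
    }
    if ((t + 1) % out_every == 0 && oi < n_out) {
      for (int i = 0; i < n; ++i) {
        bold(i, oi) = V0 * (k1 * (1.0 - q[i]) + k2 * (1.0 - q[i] / v[i])
                            + k3 * (1.0 - v[i]));
      }
      ++oi;
    }
  }
  return bold.cols(0, std::max(0, oi - 1));
}
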