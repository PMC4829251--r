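#include <Rcpp.h>
#include <vector>
#include <cmath>

// Event-driven exact simulation of the two-state AF switching process.
// Waiting times are sampled by inverting the cumulative hazard of the
// time-dependent rates (modified-Gillespie scheme); between events the rate
// components follow their closed-form deterministic solutions. Stochasticity
// enters only through unit-exponential draws from R's RNG, so a set.seed()
// on the R side makes trajectories bit-reproducible.

namespace {

const double TIME_FLOOR = 1e-12; // yr; avoids zero-length waits

struct Params {
  double A0, A1, Amax, tc, td, alpha, beta, R0, lam, mu, nu, B;
};

inline double softplus(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

inline double age_activation(double t, const Params &p) {
  return p.A1 / (1.0 + std::exp(-(t - p.tc) / p.td));
}

inline double age_recovery(double t, const Params &p) {
  return p.R0 * std::exp(-p.lam * t);
}

// integral of the total activation rate over [t, t + tau], SR dynamics
inline double sr_cum_hazard(double t, double Aepi, double tau, const Params &p) {
  double sig = p.A1 * p.td * (softplus((t + tau - p.tc) / p.td) -
                              softplus((t - p.tc) / p.td));
  double epi = p.beta > 0 ? Aepi / p.beta * (-std::expm1(-p.beta * tau))
                          : Aepi * tau;
  return p.A0 * tau + sig + epi;
}

inline double sr_rate(double t, double Aepi, double tau, const Params &p) {
  return p.A0 + age_activation(t + tau, p) + Aepi * std::exp(-p.beta * tau);
}

// solve sr_cum_hazard(tau) = E by bracketed safeguarded Newton
double invert_sr(double t, double Aepi, double E, const Params &p) {
  double tol = 1e-12 * std::max(1.0, E);
  double tau = E / sr_rate(t, Aepi, 0.0, p);
  double lo = 0.0, hi = tau;
  while (sr_cum_hazard(t, Aepi, hi, p) < E) {
    lo = hi;
    hi *= 2.0;
    if (hi > 1e12) Rcpp::stop("failed to bracket hazard inversion");
  }
  if (tau < lo) tau = lo;
  if (tau > hi) tau = hi;
  for (int i = 0; i < 200; ++i) {
    double f = sr_cum_hazard(t, Aepi, tau, p) - E;
    if (std::fabs(f) <= tol) break;
    if (f > 0) hi = tau; else lo = tau;
    double tau_new = tau - f / sr_rate(t, Aepi, tau, p);
    if (!std::isfinite(tau_new) || tau_new <= lo || tau_new >= hi)
      tau_new = 0.5 * (lo + hi);
    if (tau_new == tau) break;
    tau = tau_new;
  }
  return std::max(tau, TIME_FLOOR);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List sim_patient_cpp(Rcpp::List params, double horizon,
                           double t0, double Aepi0, double Repi0,
                           double max_episodes) {
  Params p;
  p.A0 = params["A0"];   p.A1 = params["A1"];     p.Amax = params["Amax"];
  p.tc = params["tc"];   p.td = params["td"];     p.alpha = params["alpha"];
  p.beta = params["beta"]; p.R0 = params["R0"];   p.lam = params["lam"];
  p.mu = params["mu"];   p.nu = params["nu"];     p.B = params["B"];

  double t = t0, Aepi = Aepi0, Repi = Repi0;
  int S = 0;
  std::vector<double> starts, ends;
  std::vector<int> cens;

  while (t < horizon) {
    // --- sinus rhythm: wait for next episode onset ---
    double E = R::exp_rand();
    double remaining = horizon - t;
    if (sr_cum_hazard(t, Aepi, remaining, p) < E) {
      t = horizon; // no further onset before the horizon
      break;
    }
    double tau = invert_sr(t, Aepi, E, p);
    if (tau >= remaining) { t = horizon; break; }
    Aepi *= std::exp(-p.beta * tau);
    Repi *= std::exp(-p.nu * tau);
    t += tau;
    S = 1;
    double ep_start = t;

    // --- AF: wait for termination (or never) ---
    double r_enter = age_recovery(t, p) + Repi;
    if (r_enter <= 0)
      Rcpp::stop("non-positive total recovery rate at episode start");
    E = R::exp_rand();
    double tau_af;
    bool never = false;
    if (p.mu > 0) {
      if (E >= r_enter / p.mu) never = true;
      else tau_af = std::max(-std::log1p(-p.mu * E / r_enter) / p.mu,
                             TIME_FLOOR);
    } else {
      tau_af = std::max(E / r_enter, TIME_FLOOR);
    }
    if (never || t + tau_af >= horizon) {
      starts.push_back(ep_start);
      ends.push_back(horizon);
      cens.push_back(1);
      t = horizon;
      break;
    }
    double r_tot = r_enter * std::exp(-p.mu * tau_af);
    Aepi = p.Amax - (p.Amax - Aepi) * std::exp(-p.alpha * tau_af);
    t += tau_af;
    Repi = r_tot - age_recovery(t, p);
    if (Repi < 0) Repi = -p.B * Repi; // post-episode boost
    S = 0;
    starts.push_back(ep_start);
    ends.push_back(t);
    cens.push_back(0);

    if (!std::isfinite(t) || !std::isfinite(Aepi) || !std::isfinite(Repi))
      Rcpp::stop("non-finite patient state at t = %f", t);
    if ((double)starts.size() > max_episodes)
      Rcpp::stop("episode count exceeded max_episodes (%g); "
                 "raise the cap if this parameter set is intended",
                 max_episodes);
  }

  return Rcpp::List::create(
    Rcpp::Named("start") = starts,
    Rcpp::Named("end") = ends,
    Rcpp::Named("censored") = cens,
    Rcpp::Named("final_state") = Rcpp::NumericVector::create(
      Rcpp::Named("t") = t, Rcpp::Named("S") = S,
      Rcpp::Named("Aepi") = Aepi, Rcpp::Named("Repi") = Repi));
}
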