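#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimal single-compartment SNc dopaminergic-neuron model carrying the
// CaV1.3 mechanism: HH-style Na/K spiking currents, an ohmic leak, a
// small-conductance Ca2+-activated K+ current (SK, the pacemaker's cycle
// terminator), the L-type Ca2+ current with Ca2+-driven CDI and the CMI
// two-population weighting (the non-CDI population's conductance pinned
// at the end-stage fraction r_inf_max), and a one-pool submembrane Ca2+
// with linear extrusion. Fixed-step RK4: deterministic for fixed inputs.

struct Pars {
  double cm;                 // pF
  double g_na, e_na;         // nS, mV
  double g_k, e_k;
  double g_leak, e_leak;
  double g_sk, k_sk;         // Ca2+-activated K+ (SK): nS, uM half-activation
  double g_cal, e_ca;        // CaV1.3 maximal conductance and reversal
  double vh_ca, k_ca;        // CaL activation Boltzmann
  double kappa;              // uM per pA*ms (influx-to-concentration)
  double tau_ca;             // ms, extrusion
  double k_cdi, hill_n;      // uM, Hill exponent of Ca2+-driven h_inf
  double tau_h;              // ms, CDI onset (inactivation)
  double tau_h_rec;          // ms, CDI recovery (h rising); >= tau_h
  double r_inf_max;          // end-stage remaining fraction (CDI floor)
  double v_shift_na;         // rightward shift of Na/K spike gating (mV)
  double w;                  // CMI weight
  double block;              // conventional block fraction on g_cal
};

static Pars as_pars(const List& p) {
  Pars q;
  q.cm = p["capacitance"]; q.g_na = p["g_na"]; q.e_na = p["e_na"];
  q.g_k = p["g_k"]; q.e_k = p["e_k"];
  q.g_leak = p["g_leak"]; q.e_leak = p["e_leak"];
  q.g_sk = p["g_sk"]; q.k_sk = p["k_sk"];
  q.g_cal = p["g_cal"]; q.e_ca = p["e_ca"];
  q.vh_ca = p["vh_ca"]; q.k_ca = p["k_ca"];
  q.kappa = p["kappa"]; q.tau_ca = p["tau_ca"];
  q.k_cdi = p["k_cdi"]; q.hill_n = p["hill_n"]; q.tau_h = p["tau_h"];
  q.tau_h_rec = p["tau_h_rec"];
  q.r_inf_max = p["r_inf_max"]; q.w = p["w"]; q.block = p["block_fraction"];
  q.v_shift_na = p["v_shift_na"];
  return q;
}

// classic HH rate functions (mV, 1/ms), resting near -65 mV
static inline double vtrap(double x, double y) {
  // x/(1 - exp(-x/y)) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0) ; // ~y at x->0
  return x / (1.0 - std::exp(-x / y));
}
static inline double alpha_m(double v) { return 0.1 * vtrap(v + 40.0, 10.0); }
static inline double beta_m(double v)  { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double beta_h(double v)  { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
static inline double alpha_n(double v) { return 0.01 * vtrap(v + 55.0, 10.0); }
static inline double beta_n(double v)  { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

static inline double mca_inf(double v, const Pars& p) {
  return 1.0 / (1.0 + std::exp(-(v - p.vh_ca) / p.k_ca));
}

static inline double hcdi_inf(double ca, const Pars& p) {
  double hill = std::pow(ca / p.k_cdi, p.hill_n);
  return p.r_inf_max + (1.0 - p.r_inf_max) / (1.0 + hill);
}

// I_CaL in pA; availability mixes the CDI population (gate h) with the
// CMI population pinned at the end-stage fraction
static inline double i_cal(double v, double h, const Pars& p) {
  double avail = (1.0 - p.w) * h + p.w * p.r_inf_max;
  return p.g_cal * (1.0 - p.block) * mca_inf(v, p) * avail * (v - p.e_ca);
}

// state: v, h_na, n_k, h_cdi, ca
static inline void deriv(const double* s, double* ds, const Pars& p) {
  double v = s[0], hna = s[1], nk = s[2], hc = s[3], ca = s[4];
  // spike-generating gates (Na m/h and K n) shifted right of the leak/CaL
  // frame so the subthreshold Ca2+ wave is carried by CaL, SK and leak alone
  double vna = v - p.v_shift_na;
  double am = alpha_m(vna), bm = beta_m(vna);
  double minf = am / (am + bm);
  double ina = p.g_na * minf * minf * minf * hna * (v - p.e_na);
  double ik = p.g_k * nk * nk * nk * nk * (v - p.e_k);
  double il = p.g_leak * (v - p.e_leak);
  double ca4 = ca * ca * ca * ca;
  double ksk4 = p.k_sk * p.k_sk * p.k_sk * p.k_sk;
  double isk = p.g_sk * ca4 / (ca4 + ksk4) * (v - p.e_k);
  double ica = i_cal(v, hc, p);
  ds[0] = -(ina + ik + il + isk + ica) / p.cm;
  ds[1] = alpha_h(vna) * (1.0 - hna) - beta_h(vna) * hna;
  ds[2] = alpha_n(vna) * (1.0 - nk) - beta_n(vna) * nk;
  double hinf = hcdi_inf(ca, p);
  // CDI onset is fast, recovery from inactivation slow (asymmetric kinetics)
  ds[3] = (hinf - hc) / (hinf < hc ? p.tau_h : p.tau_h_rec);
  ds[4] = -p.kappa * ica - ca / p.tau_ca;
}

// [[Rcpp::export(name = ".pacemaker_rk4")]]
List pacemaker_rk4(List params, double duration, double dt,
                   double record_dt) {
  Pars p = as_pars(params);
  long nstep = (long)std::llround(duration / dt);
  int rec_every = std::max(1, (int)std::llround(record_dt / dt));
  long nrec = nstep / rec_every + 1;

  NumericVector t_out(nrec), v_out(nrec), ca_out(nrec), ical_out(nrec);

  double s[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  // deterministic start: rest near -65 mV, HH gates at steady state there,
  // CDI gate fully available, Ca2+ at a small basal level
  double v0 = -65.0;
  double v0na = v0 - p.v_shift_na;
  s[0] = v0;
  s[1] = alpha_h(v0na) / (alpha_h(v0na) + beta_h(v0na));
  s[2] = alpha_n(v0na) / (alpha_n(v0na) + beta_n(v0na));
  s[3] = 1.0;
  s[4] = 0.05;

  long ri = 0;
  t_out[ri] = 0.0; v_out[ri] = s[0]; ca_out[ri] = s[4];
  ical_out[ri] = i_cal(s[0], s[3], p);
  ri++;

  for (long i = 1; i <= nstep; i++) {
    deriv(s, k1, p);
    for (int j = 0; j < 5; j++) tmp[j] = s[j] + 0.5 * dt * k1[j];
    deriv(tmp, k2, p);
    for (int j = 0; j < 5; j++) tmp[j] = s[j] + 0.5 * dt * k2[j];
    deriv(tmp, k3, p);
    for (int j = 0; j < 5; j++) tmp[j] = s[j] + dt * k3[j];
    deriv(tmp, k4, p);
    for (int j = 0; j < 5; j++)
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (s[4] < 0.0) s[4] = 0.0;
    if (!std::isfinite(s[0]) || std::fabs(s[0]) > 200.0) {
      stop("numerical instability at t = %f ms (|V| > 200 mV); reduce dt or check parameters",
           i * dt);
    }
    if (i % rec_every == 0 && ri < nrec) {
      t_out[ri] = i * dt; v_out[ri] = s[0]; ca_out[ri] = s[4];
      ical_out[ri] = i_cal(s[0], s[3], p);
      ri++;
    }
  }
  return List::create(_["time"] = t_out, _["v"] = v_out,
                      _["ca_sub"] = ca_out, _["i_cal"] = ical_out);
}

// Voltage-clamp harness for the same CaL mechanism: V is forced to a step
// potential while the CDI gate and submembrane Ca2+ evolve dynamically.
// [[Rcpp::export(name = ".cal_clamp_rk4")]]
List cal_clamp_rk4(List params, double v_step, double duration, double dt,
                   double record_dt) {
  Pars p = as_pars(params);
  long nstep = (long)std::llround(duration / dt);
  int rec_every = std::max(1, (int)std::llround(record_dt / dt));
  long nrec = nstep / rec_every + 1;
  NumericVector t_out(nrec), ical_out(nrec), ca_out(nrec), h_out(nrec);

  double s[2] = {1.0, 0.05};  // h_cdi, ca
  double k1[2], k2[2], k3[2], k4[2], tmp[2];
  auto d2 = [&](const double* x, double* dx) {
    double ica = i_cal(v_step, x[0], p);
    double hinf = hcdi_inf(x[1], p);
    dx[0] = (hinf - x[0]) / (hinf < x[0] ? p.tau_h : p.tau_h_rec);
    dx[1] = -p.kappa * ica - x[1] / p.tau_ca;
  };
  long ri = 0;
  t_out[ri] = 0.0; ical_out[ri] = i_cal(v_step, s[0], p);
  ca_out[ri] = s[1]; h_out[ri] = s[0]; ri++;
  for (long i = 1; i <= nstep; i++) {
    d2(s, k1);
    for (int j = 0; j < 2; j++) tmp[j] = s[j] + 0.5 * dt * k1[j];
    d2(tmp, k2);
    for (int j = 0; j < 2; j++) tmp[j] = s[j] + 0.5 * dt * k2[j];
    d2(tmp, k3);
    for (int j = 0; j < 2; j++) tmp[j] = s[j] + dt * k3[j];
    d2(tmp, k4);
    for (int j = 0; j < 2; j++)
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (s[1] < 0.0) s[1] = 0.0;
    if (i % rec_every == 0 && ri < nrec) {
      t_out[ri] = i * dt; ical_out[ri] = i_cal(v_step, s[0], p);
      ca_out[ri] = s[1]; h_out[ri] = s[0]; ri++;
    }
  }
  return List::create(_["time"] = t_out, _["i_cal"] = ical_out,
                      _["ca_sub"] = ca_out, _["h_cdi"] = h_out);
}
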