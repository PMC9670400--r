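// Three-compartment conductance-based model of a reticular thalamic
// (nRT) neuron: soma (fast Na+ / delayed-rectifier K+ spike currents,
// Traub-style kinetics) plus two dendritic sections, passive leak and
// axial coupling everywhere, and a low-threshold T-type Ca2+ current in
// every compartment. The T conductance is split into a reference-kinetics
// fraction (1-f) and a variant-kinetics fraction f with independent gate
// states, so f = 0 reproduces the reference cell exactly.
//
// Units: mV, ms, cm2, S/cm2 (densities), cm/s (Ca permeability), nS
// (axial couplings), pA (point currents), pF (capacitance).
//
// Fixed-step RK4; gate rates at 24 degC (temperature factors unity).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NV = 3;       // compartments
static const int NSTATE = 18;  // 3 v + 12 T gates + 3 somatic HH gates

struct Pars {
  double area[3];      // cm2
  double gc01, gc12;   // nS
  double cm;           // uF/cm2
  double gpas, epas;
  double gna, gk, ena, ek, vtraub;
  double pcat[3];      // cm/s
  double f;
  double cai, cao, celsius;
  // reference T steady-state constants
  double r_vha, r_ka, r_vhi, r_ki;
  // variant T kinetics: Boltzmann midpoints/slopes, tau shifts, recovery scale
  double v_vha, v_ka, v_vhi, v_ki, v_dm, v_dh, v_s;
  int pexp;
  double phi_m, phi_h;  // Q10 rate factors (5 and 3, referenced to 24 degC)
};

static Pars unpack(const NumericVector& p) {
  Pars q;
  q.area[0] = p[0]; q.area[1] = p[1]; q.area[2] = p[2];
  q.gc01 = p[3]; q.gc12 = p[4];
  q.cm = p[5]; q.gpas = p[6]; q.epas = p[7];
  q.gna = p[8]; q.gk = p[9]; q.ena = p[10]; q.ek = p[11]; q.vtraub = p[12];
  q.pcat[0] = p[13]; q.pcat[1] = p[14]; q.pcat[2] = p[15];
  q.f = p[16]; q.cai = p[17]; q.cao = p[18]; q.celsius = p[19];
  q.r_vha = p[20]; q.r_ka = p[21]; q.r_vhi = p[22]; q.r_ki = p[23];
  q.v_vha = p[24]; q.v_ka = p[25]; q.v_vhi = p[26]; q.v_ki = p[27];
  q.v_dm = p[28]; q.v_dh = p[29]; q.v_s = p[30];
  q.pexp = (int) p[31];
  q.phi_m = std::pow(5.0, (q.celsius - 24.0) / 10.0);
  q.phi_h = std::pow(3.0, (q.celsius - 24.0) / 10.0);
  return q;
}

// reference T-current time-constant curves (reduced nRT model)
static inline double tau_m_ref(double v) {
  return 3.0 + 1.0 / (std::exp((v + 27.0) / 10.0) +
                      std::exp(-(v + 102.0) / 15.0));
}
static inline double tau_h_ref(double v) {
  return 85.0 + 1.0 / (std::exp((v + 48.0) / 4.0) +
                       std::exp(-(v + 407.0) / 50.0));
}

static inline double boltz_up(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp((vh - v) / k));
}
static inline double boltz_down(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp((v - vh) / k));
}

// constant-field (GHK) flux term for Ca2+, mA/cm2 when multiplied by
// permeability (cm/s); NEURON convention, concentrations in mM
static inline double efun(double z) {
  if (std::fabs(z) < 1e-4) return 1.0 - z / 2.0;
  return z / (std::exp(z) - 1.0);
}
static inline double ghk(double v, double cai, double cao, double celsius) {
  const double FARADAY = 96485.309, R = 8.3134;
  double z = 1e-3 * 2.0 * FARADAY * v / (R * (celsius + 273.15));
  return 0.001 * 2.0 * FARADAY * (cai * efun(-z) - cao * efun(z));
}

static inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

// Somatic gate rates are capped at 40/ms: the Traub rate functions grow
// exponentially far outside the physiological range (e.g. alpha_h at
// -190 mV) where the gates are already saturated, and uncapped rates
// would force the fixed integration step below its default. The cap is
// far above every rate reached between -100 and +50 mV.
static inline double rcap(double r) { return r < 40.0 ? r : 40.0; }

// full right-hand side
static void deriv(const Pars& q, const double* y, double inj_pA,
                  double* dy) {
  const double* v = y;          // v[0..2]
  // T gates: per compartment [m_ref, h_ref, m_var, h_var]
  // somatic HH gates
  double na_m = y[15], na_h = y[16], k_n = y[17];

  double iT[3];
  for (int c = 0; c < 3; ++c) {
    const double* g = y + 3 + 4 * c;
    double gf = ghk(v[c], q.cai, q.cao, q.celsius);
    double mref = g[0], href = g[1], mvar = g[2], hvar = g[3];
    double open_ref = (q.pexp == 2 ? mref * mref : mref) * href;
    double open_var = (q.pexp == 2 ? mvar * mvar : mvar) * hvar;
    // mA/cm2
    iT[c] = q.pcat[c] * ((1.0 - q.f) * open_ref + q.f * open_var) * gf;
  }

  // somatic spike currents (mA/cm2)
  double ina = q.gna * na_m * na_m * na_m * na_h * (v[0] - q.ena);
  double ik = q.gk * k_n * k_n * k_n * k_n * (v[0] - q.ek);

  for (int c = 0; c < 3; ++c) {
    double C_pF = q.cm * q.area[c] * 1e6;
    double i_dens = q.gpas * (v[c] - q.epas) + iT[c];
    if (c == 0) i_dens += ina + ik;
    double i_pA = i_dens * q.area[c] * 1e9;
    double ax = 0.0;
    if (c == 0) ax = q.gc01 * (v[1] - v[0]);
    else if (c == 1) ax = q.gc01 * (v[0] - v[1]) + q.gc12 * (v[2] - v[1]);
    else ax = q.gc12 * (v[1] - v[2]);
    double i_in = ax - i_pA + (c == 0 ? inj_pA : 0.0);
    dy[c] = i_in / C_pF;
  }

  // T gates
  for (int c = 0; c < 3; ++c) {
    const double* g = y + 3 + 4 * c;
    double* dg = dy + 3 + 4 * c;
    double vc = v[c];
    // reference kinetics
    double mi_r = boltz_up(vc, q.r_vha, q.r_ka);
    double hi_r = boltz_down(vc, q.r_vhi, q.r_ki);
    dg[0] = (mi_r - g[0]) / (tau_m_ref(vc) / q.phi_m);
    dg[1] = (hi_r - g[1]) / (tau_h_ref(vc) / q.phi_h);
    // variant kinetics: shifted taus, recovery-scaled hyperpolarized limb
    double mi_v = boltz_up(vc, q.v_vha, q.v_ka);
    double hi_v = boltz_down(vc, q.v_vhi, q.v_ki);
    double th_v = tau_h_ref(vc - q.v_dh) / q.phi_h *
      (1.0 + (q.v_s - 1.0) / (1.0 + std::exp((vc - q.v_vhi) / 5.0)));
    dg[2] = (mi_v - g[2]) / (tau_m_ref(vc - q.v_dm) / q.phi_m);
    dg[3] = (hi_v - g[3]) / th_v;
  }

  // somatic HH gates (Traub-style, rates 1/ms)
  double v2 = v[0] - q.vtraub;
  double am = rcap(0.32 * vtrap(13.0 - v2, 4.0));
  double bm = rcap(0.28 * vtrap(v2 - 40.0, 5.0));
  double ah = rcap(0.128 * std::exp((17.0 - v2) / 18.0));
  double bh = rcap(4.0 / (1.0 + std::exp((40.0 - v2) / 5.0)));
  double an = rcap(0.032 * vtrap(15.0 - v2, 5.0));
  double bn = rcap(0.5 * std::exp((10.0 - v2) / 40.0));
  dy[15] = am * (1.0 - na_m) - bm * na_m;
  dy[16] = ah * (1.0 - na_h) - bh * na_h;
  dy[17] = an * (1.0 - k_n) - bn * k_n;
}

// [[Rcpp::export(name = ".nrt_init_state_cpp")]]
NumericVector nrt_init_state_cpp(NumericVector par, double v0) {
  Pars q = unpack(par);
  NumericVector y(NSTATE);
  for (int c = 0; c < 3; ++c) {
    y[c] = v0;
    y[3 + 4 * c + 0] = boltz_up(v0, q.r_vha, q.r_ka);
    y[3 + 4 * c + 1] = boltz_down(v0, q.r_vhi, q.r_ki);
    y[3 + 4 * c + 2] = boltz_up(v0, q.v_vha, q.v_ka);
    y[3 + 4 * c + 3] = boltz_down(v0, q.v_vhi, q.v_ki);
  }
  double v2 = v0 - q.vtraub;
  double am = rcap(0.32 * vtrap(13.0 - v2, 4.0));
  double bm = rcap(0.28 * vtrap(v2 - 40.0, 5.0));
  double ah = rcap(0.128 * std::exp((17.0 - v2) / 18.0));
  double bh = rcap(4.0 / (1.0 + std::exp((40.0 - v2) / 5.0)));
  double an = rcap(0.032 * vtrap(15.0 - v2, 5.0));
  double bn = rcap(0.5 * std::exp((10.0 - v2) / 40.0));
  y[15] = am / (am + bm);
  y[16] = ah / (ah + bh);
  y[17] = an / (an + bn);
  return y;
}

// Integrate over a schedule of (duration, injected current) phases.
// Records every `record_every` steps (plus the initial sample).
// [[Rcpp::export(name = ".nrt_run_cpp")]]
List nrt_run_cpp(NumericVector par, NumericVector y0, double dt,
                 NumericVector durations, NumericVector inj_pA,
                 int record_every) {
  if (durations.size() != inj_pA.size())
    stop("durations and injections must have equal length");
  Pars q = unpack(par);
  double y[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE],
      tmp[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];

  long total_steps = 0;
  std::vector<long> phase_steps(durations.size());
  for (int p = 0; p < durations.size(); ++p) {
    phase_steps[p] = (long) std::lround(durations[p] / dt);
    total_steps += phase_steps[p];
  }
  long n_rec = total_steps / record_every + 1;
  NumericVector t_out(n_rec);
  NumericMatrix v_out(n_rec, NV);

  long step = 0, rec = 0;
  t_out[0] = 0.0;
  for (int c = 0; c < NV; ++c) v_out(0, c) = y[c];
  rec = 1;

  for (int p = 0; p < durations.size(); ++p) {
    double inj = inj_pA[p];
    for (long s = 0; s < phase_steps[p]; ++s) {
      deriv(q, y, inj, k1);
      for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
      deriv(q, tmp, inj, k2);
      for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
      deriv(q, tmp, inj, k3);
      for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + dt * k3[i];
      deriv(q, tmp, inj, k4);
      for (int i = 0; i < NSTATE; ++i)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      ++step;
      if (!std::isfinite(y[0]) || std::fabs(y[0]) > 500.0)
        stop("numerical instability at t = %f ms (v_soma = %f); "
             "reduce dt", step * dt, y[0]);
      if (step % record_every == 0 && rec < n_rec) {
        t_out[rec] = step * dt;
        for (int c = 0; c < NV; ++c) v_out(rec, c) = y[c];
        ++rec;
      }
    }
  }
  NumericVector yend(NSTATE);
  for (int i = 0; i < NSTATE; ++i) yend[i] = y[i];
  return List::create(_["time"] = t_out, _["v"] = v_out,
                      _["state_end"] = yend);
}
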