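// Fixed-step (forward Euler) integration engines for the LSO point-neuron
// models, plus the event-driven coincidence counter. Canonical units
// throughout: time ms, potential mV, conductance nS, current pA,
// capacitance pF (so nS*mV = pA and pF/nS = ms).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Map a spike time (ms) to its nearest grid index.
inline R_xlen_t spike_index(double t, double dt) {
  return (R_xlen_t) std::llround(t / dt);
}

// Linearly summed alpha kernels, exact per-step recursion.
// State a decays as exp(-dt/tau); g obeys g' = (a - g)/tau-like coupling:
//   g_{n+1} = E * (g_n + (dt/tau) * a_n),  a_{n+1} = E * a_n,
// and an arrival adds amp*e to a, so a single event gives
//   g(t) = amp * (t/tau) * exp(1 - t/tau)  exactly at grid points.
struct AlphaState {
  double a = 0.0, g = 0.0;
  double E, dt_over_tau, amp_e;
  AlphaState(double amp, double tau, double dt)
    : E(std::exp(-dt / tau)), dt_over_tau(dt / tau), amp_e(amp * std::exp(1.0)) {}
  inline void step() { g = E * (g + dt_over_tau * a); a = E * a; }
  inline void add(int count) { a += amp_e * count; }
  inline void clear() { a = 0.0; g = 0.0; }
};

// Single-exponential kernels (exponential Stein model): value amp at onset.
struct ExpState {
  double g = 0.0;
  double E, amp;
  ExpState(double amp_, double tau, double dt) : E(std::exp(-dt / tau)), amp(amp_) {}
  inline void step() { g *= E; }
  inline void add(int count) { g += amp * count; }
  inline void clear() { g = 0.0; }
};

// Per-step arrival counts, sparse: sorted spike indices.
struct ArrivalCursor {
  const std::vector<R_xlen_t>& idx;
  size_t pos = 0;
  explicit ArrivalCursor(const std::vector<R_xlen_t>& i) : idx(i) {}
  inline int take(R_xlen_t n) {
    int c = 0;
    while (pos < idx.size() && idx[pos] == n) { ++c; ++pos; }
    return c;
  }
};

std::vector<R_xlen_t> make_indices(const NumericVector& t, double dt, R_xlen_t nmax) {
  std::vector<R_xlen_t> out;
  out.reserve(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i) {
    R_xlen_t k = spike_index(t[i], dt);
    if (k >= 0 && k <= nmax) out.push_back(k);
  }
  std::sort(out.begin(), out.end());
  return out;
}

// External current: scalar (constant) or one value per grid point.
struct ExtCurrent {
  const NumericVector& I;
  bool scalar;
  explicit ExtCurrent(const NumericVector& I_) : I(I_), scalar(I_.size() == 1) {}
  inline double at(R_xlen_t n) const { return scalar ? I[0] : I[std::min(n, (R_xlen_t)I.size() - 1)]; }
};

// Rothman-Manis gate kinetics (guinea-pig VCN), voltages pre-shifted by Vshift.
struct RMGates {
  // order: w, z, n, p, m, h
  static void eval(double V, double* xinf, double* taux) {
    xinf[0] = std::pow(1.0 / (1.0 + std::exp(-(V + 48.0) / 6.0)), 0.25);
    taux[0] = 1.5 + 100.0 / (6.0 * std::exp((V + 60.0) / 6.0) + 16.0 * std::exp(-(V + 60.0) / 45.0));
    xinf[1] = 0.5 + 0.5 / (1.0 + std::exp((V + 71.0) / 10.0));
    taux[1] = 50.0 + 1000.0 / (std::exp((V + 60.0) / 20.0) + std::exp(-(V + 60.0) / 8.0));
    xinf[2] = std::sqrt(1.0 / (1.0 + std::exp(-(V + 15.0) / 5.0)));
    taux[2] = 0.7 + 100.0 / (11.0 * std::exp((V + 60.0) / 24.0) + 21.0 * std::exp(-(V + 60.0) / 23.0));
    xinf[3] = 1.0 / (1.0 + std::exp(-(V + 23.0) / 6.0));
    taux[3] = 5.0 + 100.0 / (4.0 * std::exp((V + 60.0) / 32.0) + 5.0 * std::exp(-(V + 60.0) / 22.0));
    xinf[4] = 1.0 / (1.0 + std::exp(-(V + 38.0) / 7.0));
    taux[4] = 0.04 + 10.0 / (5.0 * std::exp((V + 60.0) / 18.0) + 36.0 * std::exp(-(V + 60.0) / 25.0));
    xinf[5] = 1.0 / (1.0 + std::exp((V + 65.0) / 6.0));
    taux[5] = 0.6 + 100.0 / (7.0 * std::exp((V + 60.0) / 11.0) + 10.0 * std::exp(-(V + 60.0) / 25.0));
  }
};

// Lookup table over raw membrane voltage for the six RM gates.
struct GateTable {
  double vmin = -200.0, vmax = 120.0, dv = 0.025;
  int n;
  std::vector<double> xinf[6], rate[6]; // rate = 1/tau
  GateTable(double vshift) {
    n = (int) std::llround((vmax - vmin) / dv) + 1;
    double xi[6], tx[6];
    for (int g = 0; g < 6; ++g) { xinf[g].resize(n); rate[g].resize(n); }
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * dv;
      RMGates::eval(V - vshift, xi, tx);
      for (int g = 0; g < 6; ++g) { xinf[g][i] = xi[g]; rate[g][i] = 1.0 / tx[g]; }
    }
  }
  inline void interp(double V, double* xi, double* rt) const {
    double u = (V - vmin) / dv;
    if (u < 0) u = 0;
    if (u > n - 1.001) u = n - 1.001;
    int i = (int) u;
    double f = u - i;
    for (int g = 0; g < 6; ++g) {
      xi[g] = xinf[g][i] + f * (xinf[g][i + 1] - xinf[g][i]);
      rt[g] = rate[g][i] + f * (rate[g][i + 1] - rate[g][i]);
    }
  }
};

} // namespace

// ---------------------------------------------------------------------------
// Coincidence counting model (event-driven).
// C(t) = #ex in (t - Wex, t] - H * #inh in (t - Winh, t]; output spike when
// C >= theta at an excitatory arrival and t >= last_spike + Tref.
// [[Rcpp::export]]
NumericVector cc_run(NumericVector ex, NumericVector inh,
                     double tref, double theta, double wex,
                     double H, double winh) {
  std::vector<double> out;
  R_xlen_t ne = ex.size(), ni = inh.size();
  R_xlen_t lo_e = 0, lo_i = 0, hi_i = 0;
  double last = -1e18;
  // EPS absorbs floating-point error at the half-open window boundary: a
  // spike exactly W in the past has left the window.
  const double EPS = 1e-9;
  for (R_xlen_t j = 0; j < ne; ++j) {
    double t = ex[j];
    while (lo_e < ne && ex[lo_e] <= t - wex + EPS) ++lo_e;
    // excitatory count in (t - wex, t]: include ties at t
    R_xlen_t hi_e = j;
    while (hi_e + 1 < ne && ex[hi_e + 1] <= t) ++hi_e;
    double ce = (double)(hi_e - lo_e + 1);
    while (lo_i < ni && inh[lo_i] <= t - winh + EPS) ++lo_i;
    while (hi_i < ni && inh[hi_i] <= t) ++hi_i;
    double ci = (double)(hi_i - lo_i);
    double C = ce - H * ci;
    if (C >= theta && t >= last + tref - EPS) {
      out.push_back(t);
      last = t;
    }
  }
  return wrap(out);
}

// Grid-sampled coincidence count trace (no refractory semantics), for
// inspection/plotting parity with the other models.
// [[Rcpp::export]]
NumericVector cc_count_trace(NumericVector ex, NumericVector inh,
                             double wex, double H, double winh,
                             double dt, double t_end) {
  R_xlen_t n = (R_xlen_t) std::llround(t_end / dt);
  NumericVector out(n + 1);
  R_xlen_t lo_e = 0, hi_e = 0, lo_i = 0, hi_i = 0;
  const double EPS = 1e-9;
  for (R_xlen_t k = 0; k <= n; ++k) {
    double t = k * dt;
    while (lo_e < ex.size() && ex[lo_e] <= t - wex + EPS) ++lo_e;
    while (hi_e < ex.size() && ex[hi_e] <= t) ++hi_e;
    while (lo_i < inh.size() && inh[lo_i] <= t - winh + EPS) ++lo_i;
    while (hi_i < inh.size() && inh[hi_i] <= t) ++hi_i;
    out[k] = (double)(hi_e - lo_e) - H * (double)(hi_i - lo_i);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Stein models (exponential or alpha kernels), step-based threshold check.
// kind: 0 = exponential, 1 = alpha. Excitatory amplitude fixed to 1;
// inhibitory amplitude H (subtracted).
// [[Rcpp::export]]
List stein_run(NumericVector ex, NumericVector inh, int kind,
               double tref, double theta, double tau_ex,
               double H, double tau_inh,
               double dt, double t_end,
               int record_every, bool discard_ref_inputs) {
  R_xlen_t n = (R_xlen_t) std::llround(t_end / dt);
  std::vector<R_xlen_t> exi = make_indices(ex, dt, n);
  std::vector<R_xlen_t> ini = make_indices(inh, dt, n);
  ArrivalCursor cur_e(exi), cur_i(ini);

  ExpState ee(1.0, tau_ex, dt), ei(H, tau_inh, dt);
  AlphaState ae(1.0, tau_ex, dt), ai(H, tau_inh, dt);

  std::vector<double> spikes, tr_t, tr_v;
  R_xlen_t ref_end = -1, ref_steps = (R_xlen_t) std::llround(tref / dt);

  for (R_xlen_t k = 0; k <= n; ++k) {
    if (k > 0) {
      if (kind == 0) { ee.step(); ei.step(); } else { ae.step(); ai.step(); }
    }
    int ce = cur_e.take(k), ci = cur_i.take(k);
    bool refr = (k <= ref_end);
    if (!(refr && discard_ref_inputs)) {
      if (kind == 0) { ee.add(ce); ei.add(ci); } else { ae.add(ce); ai.add(ci); }
    }
    double v = (kind == 0) ? (ee.g - ei.g) : (ae.g - ai.g);
    double v_out = refr ? 0.0 : v;
    if (!refr && v >= theta) {
      spikes.push_back(k * dt);
      if (kind == 0) { ee.clear(); ei.clear(); } else { ae.clear(); ai.clear(); }
      ref_end = k + ref_steps;
      v_out = 0.0;
    }
    if (record_every > 0 && k % record_every == 0) {
      tr_t.push_back(k * dt);
      tr_v.push_back(v_out);
    }
  }
  return List::create(_["spikes"] = wrap(spikes),
                      _["t"] = wrap(tr_t), _["v"] = wrap(tr_v));
}

// ---------------------------------------------------------------------------
// Synaptic drive alone: total alpha-kernel conductances on the full grid.
// [[Rcpp::export]]
List syn_drive_run(NumericVector ex, NumericVector inh,
                   double A_ex, double tau_ex, double A_inh, double tau_inh,
                   double dt, double t_end) {
  R_xlen_t n = (R_xlen_t) std::llround(t_end / dt);
  std::vector<R_xlen_t> exi = make_indices(ex, dt, n);
  std::vector<R_xlen_t> ini = make_indices(inh, dt, n);
  ArrivalCursor cur_e(exi), cur_i(ini);
  AlphaState ge(A_ex, tau_ex, dt), gi(A_inh, tau_inh, dt);
  NumericVector t(n + 1), g_ex(n + 1), g_inh(n + 1);
  for (R_xlen_t k = 0; k <= n; ++k) {
    if (k > 0) { ge.step(); gi.step(); }
    ge.add(cur_e.take(k));
    gi.add(cur_i.take(k));
    t[k] = k * dt;
    g_ex[k] = ge.g;
    g_inh[k] = gi.g;
  }
  return List::create(_["t"] = t, _["g_ex"] = g_ex, _["g_inh"] = g_inh);
}

// ---------------------------------------------------------------------------
// Passive integrate-and-fire model.
// [[Rcpp::export]]
List passive_if_run(NumericVector ex, NumericVector inh,
                    double A_ex, double tau_ex, double A_inh, double tau_inh,
                    double E_ex, double E_inh,
                    double C, double gL, double EL,
                    double Vreset, double Vtheta, double tref,
                    double dt, double t_end, NumericVector iext,
                    bool spikes_enabled, int record_every, double v0) {
  R_xlen_t n = (R_xlen_t) std::llround(t_end / dt);
  std::vector<R_xlen_t> exi = make_indices(ex, dt, n);
  std::vector<R_xlen_t> ini = make_indices(inh, dt, n);
  ArrivalCursor cur_e(exi), cur_i(ini);
  AlphaState ge(A_ex, tau_ex, dt), gi(A_inh, tau_inh, dt);
  ExtCurrent Ix(iext);

  double V = v0;
  std::vector<double> spikes, tr_t, tr_v, tr_ge, tr_gi;
  R_xlen_t ref_end = -1, ref_steps = (R_xlen_t) std::llround(tref / dt);
  ge.add(cur_e.take(0));
  gi.add(cur_i.take(0));

  for (R_xlen_t k = 0; k <= n; ++k) {
    if (record_every > 0 && k % record_every == 0) {
      tr_t.push_back(k * dt); tr_v.push_back(V);
      tr_ge.push_back(ge.g); tr_gi.push_back(gi.g);
    }
    if (k == n) break;
    double I = gL * (EL - V) + ge.g * (E_ex - V) + gi.g * (E_inh - V) + Ix.at(k);
    double Vn = V + dt * I / C;
    ge.step(); gi.step();
    ge.add(cur_e.take(k + 1));
    gi.add(cur_i.take(k + 1));
    if (k + 1 <= ref_end) {
      Vn = Vreset;
    } else if (spikes_enabled && Vn >= Vtheta) {
      spikes.push_back((k + 1) * dt);
      Vn = Vreset;
      ref_end = k + 1 + ref_steps;
    }
    if (!std::isfinite(Vn)) stop("passive IF: non-finite membrane potential at t = %f ms", (k + 1) * dt);
    V = Vn;
  }
  return List::create(_["spikes"] = wrap(spikes), _["t"] = wrap(tr_t),
                      _["v"] = wrap(tr_v), _["g_ex"] = wrap(tr_ge),
                      _["g_inh"] = wrap(tr_gi), _["v_end"] = V);
}

// ---------------------------------------------------------------------------
// Active integrate-and-fire model: leak + KLVA (gate d) + spike-associated
// current (sum of two exponentials, pA), no potential reset.
// [[Rcpp::export]]
List active_if_run(NumericVector ex, NumericVector inh,
                   double A_ex, double tau_ex, double A_inh, double tau_inh,
                   double E_ex, double E_inh,
                   double C, double gL, double gKL, double EL, double EK,
                   double Vtheta, double tref,
                   double isp_a1, double isp_tau1, double isp_a2, double isp_tau2,
                   double dt, double t_end, NumericVector iext,
                   bool spikes_enabled, int record_every, double v0) {
  R_xlen_t n = (R_xlen_t) std::llround(t_end / dt);
  std::vector<R_xlen_t> exi = make_indices(ex, dt, n);
  std::vector<R_xlen_t> ini = make_indices(inh, dt, n);
  ArrivalCursor cur_e(exi), cur_i(ini);
  AlphaState ge(A_ex, tau_ex, dt), gi(A_inh, tau_inh, dt);
  ExtCurrent Ix(iext);

  double V = v0;
  // KLVA gate, symmetric exponential rates alpha/beta = 0.5 exp(+-(V+50)/16)
  double d = 1.0 / (1.0 + std::exp(-(V + 50.0) / 8.0)); // d_inf(v0)
  double isp1 = 0.0, isp2 = 0.0;
  const double E1 = std::exp(-dt / isp_tau1), E2 = std::exp(-dt / isp_tau2);
  double dmin = d, dmax = d;

  std::vector<double> spikes, tr_t, tr_v, tr_d;
  R_xlen_t ref_end = -1, ref_steps = (R_xlen_t) std::llround(tref / dt);
  ge.add(cur_e.take(0));
  gi.add(cur_i.take(0));

  for (R_xlen_t k = 0; k <= n; ++k) {
    if (record_every > 0 && k % record_every == 0) {
      tr_t.push_back(k * dt); tr_v.push_back(V); tr_d.push_back(d);
    }
    if (k == n) break;
    double I = gL * (EL - V) + gKL * d * (EK - V)
             + ge.g * (E_ex - V) + gi.g * (E_inh - V)
             + (isp1 - isp2) + Ix.at(k);
    // rate-capped Euler gate step: never overshoots d_inf, so d stays in [0,1]
    double xx = (V + 50.0) / 16.0;
    if (xx > 30.0) xx = 30.0;
    if (xx < -30.0) xx = -30.0;
    double d_inf = 1.0 / (1.0 + std::exp(-2.0 * xx));
    double rate = std::cosh(xx); // alpha + beta = cosh((V+50)/16), 1/ms
    double step_frac = dt * rate;
    if (step_frac > 1.0) step_frac = 1.0;
    double Vn = V + dt * I / C;
    double dn = d + step_frac * (d_inf - d);
    isp1 *= E1; isp2 *= E2;
    ge.step(); gi.step();
    ge.add(cur_e.take(k + 1));
    gi.add(cur_i.take(k + 1));
    if (spikes_enabled && k + 1 > ref_end && Vn >= Vtheta) {
      spikes.push_back((k + 1) * dt);
      isp1 += isp_a1; isp2 += isp_a2;
      ref_end = k + 1 + ref_steps;
    }
    if (!std::isfinite(Vn)) stop("active IF: non-finite membrane potential at t = %f ms", (k + 1) * dt);
    V = Vn; d = dn;
    if (d < dmin) dmin = d;
    if (d > dmax) dmax = d;
  }
  return List::create(_["spikes"] = wrap(spikes), _["t"] = wrap(tr_t),
                      _["v"] = wrap(tr_v), _["d"] = wrap(tr_d),
                      _["v_end"] = V, _["gate_min"] = dmin, _["gate_max"] = dmax);
}

// ---------------------------------------------------------------------------
// Wang-Colburn HH-type model (Rothman-Manis kinetics), 6 gates w,z,n,p,m,h.
// Spike detection by -30 / -45 mV hysteresis; spike time = upward -30 mV
// crossing, counted once repolarization below -45 mV confirms it.
// [[Rcpp::export]]
List wc_run(NumericVector ex, NumericVector inh,
            double A_ex, double tau_ex, double A_inh, double tau_inh,
            double E_ex, double E_inh,
            double C, double gL, double gKL, double gKH, double gNa,
            double EL, double EK, double ENa,
            double Vshift, double phi,
            double dt, double t_end, NumericVector iext,
            int record_every, double v0,
            double v_arm = -30.0, double v_disarm = -45.0) {
  R_xlen_t n = (R_xlen_t) std::llround(t_end / dt);
  std::vector<R_xlen_t> exi = make_indices(ex, dt, n);
  std::vector<R_xlen_t> ini = make_indices(inh, dt, n);
  ArrivalCursor cur_e(exi), cur_i(ini);
  AlphaState ge(A_ex, tau_ex, dt), gi(A_inh, tau_inh, dt);
  ExtCurrent Ix(iext);
  GateTable tab(Vshift);

  double V = v0;
  double x[6], xi[6], rt[6];
  tab.interp(V, xi, rt);
  for (int g = 0; g < 6; ++g) x[g] = xi[g];
  double gmin = 1.0, gmax = 0.0;
  for (int g = 0; g < 6; ++g) { gmin = std::min(gmin, x[g]); gmax = std::max(gmax, x[g]); }

  std::vector<double> spikes, tr_t, tr_v;
  std::vector<double> tr_x[6];
  bool armed = false;
  double t_arm = 0.0;

  ge.add(cur_e.take(0));
  gi.add(cur_i.take(0));

  for (R_xlen_t k = 0; k <= n; ++k) {
    if (record_every > 0 && k % record_every == 0) {
      tr_t.push_back(k * dt); tr_v.push_back(V);
      for (int g = 0; g < 6; ++g) tr_x[g].push_back(x[g]);
    }
    if (k == n) break;
    double w4z = x[0] * x[0] * x[0] * x[0] * x[1];
    double khva = 0.85 * x[2] * x[2] + 0.15 * x[3];
    double m3h = x[4] * x[4] * x[4] * x[5];
    double I = gL * (EL - V) + gKL * w4z * (EK - V) + gKH * khva * (EK - V)
             + gNa * m3h * (ENa - V)
             + ge.g * (E_ex - V) + gi.g * (E_inh - V) + Ix.at(k);
    double Vn = V + dt * I / C;
    tab.interp(V, xi, rt);
    for (int g = 0; g < 6; ++g) {
      double step_frac = dt * phi * rt[g];
      if (step_frac > 1.0) step_frac = 1.0; // rate cap: no overshoot past x_inf
      x[g] += step_frac * (xi[g] - x[g]);
      if (x[g] < gmin) gmin = x[g];
      if (x[g] > gmax) gmax = x[g];
    }
    ge.step(); gi.step();
    ge.add(cur_e.take(k + 1));
    gi.add(cur_i.take(k + 1));
    if (!armed && Vn >= v_arm && V < v_arm) {
      armed = true;
      t_arm = (k + 1) * dt;
    } else if (armed && Vn < v_disarm) {
      spikes.push_back(t_arm);
      armed = false;
    }
    if (!std::isfinite(Vn)) stop("Wang-Colburn: non-finite membrane potential at t = %f ms", (k + 1) * dt);
    V = Vn;
  }
  List trace = List::create(_["t"] = wrap(tr_t), _["v"] = wrap(tr_v),
                            _["w"] = wrap(tr_x[0]), _["z"] = wrap(tr_x[1]),
                            _["n"] = wrap(tr_x[2]), _["p"] = wrap(tr_x[3]),
                            _["m"] = wrap(tr_x[4]), _["h"] = wrap(tr_x[5]));
  return List::create(_["spikes"] = wrap(spikes), _["trace"] = trace,
                      _["v_end"] = V, _["gate_min"] = gmin, _["gate_max"] = gmax);
}

// Direct (non-tabulated) Rothman-Manis gate evaluation, for cross-checking
// the lookup table and for the user-facing gate function.
// [[Rcpp::export]]
List rm_gates_cpp(NumericVector V, double Vshift) {
  R_xlen_t n = V.size();
  NumericMatrix xinf(n, 6), taux(n, 6);
  double xi[6], tx[6];
  for (R_xlen_t i = 0; i < n; ++i) {
    RMGates::eval(V[i] - Vshift, xi, tx);
    for (int g = 0; g < 6; ++g) { xinf(i, g) = xi[g]; taux(i, g) = tx[g]; }
  }
  colnames(xinf) = CharacterVector::create("w", "z", "n", "p", "m", "h");
  colnames(taux) = CharacterVector::create("w", "z", "n", "p", "m", "h");
  return List::create(_["x_inf"] = xinf, _["tau_x"] = taux);
}

// Table-interpolated gate evaluation (same path the wc engine uses).
// [[Rcpp::export]]
List wc_gate_table_interp(NumericVector V, double Vshift) {
  GateTable tab(Vshift);
  R_xlen_t n = V.size();
  NumericMatrix xinf(n, 6), taux(n, 6);
  double xi[6], rt[6];
  for (R_xlen_t i = 0; i < n; ++i) {
    tab.interp(V[i], xi, rt);
    for (int g = 0; g < 6; ++g) { xinf(i, g) = xi[g]; taux(i, g) = 1.0 / rt[g]; }
  }
  colnames(xinf) = CharacterVector::create("w", "z", "n", "p", "m", "h");
  colnames(taux) = CharacterVector::create("w", "z", "n", "p", "m", "h");
  return List::create(_["x_inf"] = xinf, _["tau_x"] = taux);
}
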