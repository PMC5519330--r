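// Implicit finite-difference integrator for the multicompartment axon cable
// equation with Hodgkin-Huxley-type channels and an electrogenic Na+/K+ pump.
//
// Scheme (NEURON-like staggering): gates are advanced by exponential Euler
// using V at the current step (exact for the linear gate ODE at frozen V),
// then the membrane equation, linear in V_{n+1} once conductances are known,
// is solved by backward Euler with the diffusion term treated implicitly
// (Thomas tridiagonal solve). Sealed (zero-flux) ends.
//
// Gate kinetics enter through per-gate lookup tables sampled on a uniform
// voltage grid: x_inf(V) and a(V) = exp(-dt/tau(V)); linear interpolation.
// Intracellular Na+ and the pump current are slow variables and are
// refreshed every `slow_stride` steps.
//
// Units: mV, ms, mS/cm2, uA/cm2, uF/cm2, mM.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct GateTable {
  const double* xinf;
  const double* afac;
};

inline void lerp2(const GateTable& g, double pos, int last,
                  double& xinf, double& afac) {
  if (pos <= 0.0) { xinf = g.xinf[0]; afac = g.afac[0]; return; }
  if (pos >= last) { xinf = g.xinf[last]; afac = g.afac[last]; return; }
  int i = (int)pos;
  double w = pos - i;
  xinf = g.xinf[i] + w * (g.xinf[i + 1] - g.xinf[i]);
  afac = g.afac[i] + w * (g.afac[i + 1] - g.afac[i]);
}

inline double ipow(double x, int p) {
  double r = 1.0;
  while (p-- > 0) r *= x;
  return r;
}

// per-site online spike detector (threshold crossing + peak refinement)
struct SpikeDetector {
  double thr, dt;
  bool in_spike;
  double v_prev;
  // trough tracking (between spikes)
  double min_v;
  // peak tracking (inside spike)
  double pk_v, pk_vm1, pk_vp1;
  long pk_step;
  bool pk_vp1_set;
  double cross_t, cross_trough;

  std::vector<double> t_cross, v_trough, v_peak, t_peak;

  void init(double threshold, double dt_, double v0) {
    thr = threshold; dt = dt_; in_spike = false; v_prev = v0;
    min_v = v0; pk_step = -1; pk_vp1_set = false;
    cross_t = 0.0; cross_trough = v0;
  }

  // returns true when a crossing is registered at this step
  bool step(long n, double v) {
    bool crossed = false;
    double t = (n + 1) * dt; // v is V at step n+1
    if (!in_spike) {
      if (v < min_v) min_v = v;
      if (v_prev < thr && v >= thr) {
        cross_t = t - dt + dt * (thr - v_prev) / (v - v_prev);
        cross_trough = min_v;
        in_spike = true;
        pk_v = v; pk_vm1 = v_prev; pk_step = n; pk_vp1_set = false;
        crossed = true;
      }
    } else {
      if (!pk_vp1_set && n == pk_step + 1) { pk_vp1 = v; pk_vp1_set = true; }
      if (v > pk_v) {
        pk_vm1 = v_prev; pk_v = v; pk_step = n; pk_vp1_set = false;
      }
      if (v < thr) { // spike over: finalize
        double tp = (pk_step + 1) * dt, vp = pk_v;
        if (pk_vp1_set) {
          double den = pk_vm1 - 2.0 * pk_v + pk_vp1;
          if (den < -1e-12) {
            double d = 0.5 * (pk_vm1 - pk_vp1) / den;
            tp += d * dt;
            vp = pk_v - 0.25 * (pk_vm1 - pk_vp1) * d;
          }
        }
        t_cross.push_back(cross_t);
        v_trough.push_back(cross_trough);
        v_peak.push_back(vp);
        t_peak.push_back(tp);
        in_spike = false;
        min_v = v;
      }
    }
    v_prev = v;
    return crossed;
  }
};

} // namespace

// [[Rcpp::export(name = ".cable_run")]]
List cable_run(List cfg, List state) {
  const int nc = as<int>(cfg["n_comp"]);
  const double dt = as<double>(cfg["dt"]);
  const long n_steps = (long)as<double>(cfg["n_steps"]);
  const double cm = as<double>(cfg["cm"]);
  const double gc = as<double>(cfg["g_couple"]); // mS/cm2 between neighbours

  // channels (copied into plain vectors: hot-loop access)
  std::vector<double> gbar = as<std::vector<double>>(cfg["gbar"]);
  std::vector<double> erev = as<std::vector<double>>(cfg["erev"]);
  std::vector<int> pexp = as<std::vector<int>>(cfg["p"]);
  std::vector<int> qexp = as<std::vector<int>>(cfg["q"]);
  std::vector<int> im = as<std::vector<int>>(cfg["gate_m"]); // table column, -1 none
  std::vector<int> ih = as<std::vector<int>>(cfg["gate_h"]);
  const int nch = (int)gbar.size();
  const int ina = as<int>(cfg["i_na"]); // Na channel index or -1 (dynamic ENa)

  NumericMatrix xinf_tab = cfg["xinf_tab"];
  NumericMatrix afac_tab = cfg["afac_tab"];
  const int ntab = xinf_tab.nrow();
  const int ngate = xinf_tab.ncol();
  const double vmin = as<double>(cfg["v_tab_min"]);
  const double dv_inv = 1.0 / as<double>(cfg["v_tab_step"]);
  std::vector<GateTable> gt(ngate);
  for (int g = 0; g < ngate; ++g) {
    gt[g].xinf = &xinf_tab(0, g);
    gt[g].afac = &afac_tab(0, g);
  }

  // pump / sodium
  const int pump_mode = as<int>(cfg["pump_mode"]); // 0 none, 1 dynamic, 2 constant
  const double imax = as<double>(cfg["pump_imax"]);
  const double na_half = as<double>(cfg["pump_na_half"]);
  const double na_s = as<double>(cfg["pump_na_s"]);
  const double ipump_const = as<double>(cfg["ipump_const"]);
  const double na_conv = as<double>(cfg["na_conv"]); // mM per (uA/cm2 * ms)
  const double na_out = as<double>(cfg["na_out"]);
  const double ena_scale = as<double>(cfg["ena_scale"]);
  const int slow_stride = as<int>(cfg["slow_stride"]);

  // stimulus (one shared amplitude/width; onsets in steps)
  std::vector<double> stim_on = as<std::vector<double>>(cfg["stim_onset_step"]);
  const long n_stim = (long)stim_on.size();
  const long width_steps = (long)as<double>(cfg["stim_width_steps"]);
  const double stim_amp = as<double>(cfg["stim_amp_density"]); // uA/cm2
  const int stim_comp = as<int>(cfg["stim_comp"]);

  // recording
  const int s1 = as<int>(cfg["site1"]);
  const int s2 = as<int>(cfg["site2"]);
  const double thr = as<double>(cfg["threshold"]);
  const long trace_stride = (long)as<double>(cfg["trace_stride"]);
  const long sample_stride = (long)as<double>(cfg["sample_stride"]);

  // state
  NumericVector V0 = state["v"];
  NumericMatrix G0 = state["gates"]; // nc x ngate
  NumericVector Na0 = state["na_in"];
  double t0 = as<double>(state["t_ms"]);

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> gates(G0.begin(), G0.end()); // column-major nc x ngate
  std::vector<double> na(Na0.begin(), Na0.end());
  std::vector<double> ena(nc), ipump(nc), gna(nc);

  for (int i = 0; i < nc; ++i) {
    ena[i] = ena_scale * 58.0 * std::log10(na_out / na[i]);
    if (pump_mode == 1)
      ipump[i] = imax / (1.0 + std::exp((na_half - na[i]) / na_s));
    else if (pump_mode == 2)
      ipump[i] = ipump_const;
    else
      ipump[i] = 0.0;
  }

  // Thomas solver workspace
  std::vector<double> diag(nc), rhs(nc), cp(nc), dp(nc);
  const double cdt = cm / dt;

  SpikeDetector det1, det2;
  det1.init(thr, dt, V[s1]);
  det2.init(thr, dt, V[s2]);

  // site-1 per-spike auxiliary snapshots
  std::vector<double> sp_ena, sp_na;
  std::vector<double> sp_gates_peak, sp_gates_trough; // ngate per spike
  std::vector<double> cur_gpeak(ngate), cur_gtrough(ngate);
  double cur_pk_v = -1e300;
  bool s1_in_spike_prev = false;

  std::vector<double> tr_t, tr_v1, tr_v2;
  std::vector<double> smp_t, smp_ipump, smp_na;
  double sum_ina = 0.0, sum_ipump = 0.0;

  long stim_ptr = 0;

  for (long n = 0; n < n_steps; ++n) {
    // advance stimulus pointer; active if onset <= n < onset+width
    double istim = 0.0;
    while (stim_ptr < n_stim && stim_on[stim_ptr] + width_steps <= n) ++stim_ptr;
    if (stim_ptr < n_stim && stim_on[stim_ptr] <= n) istim = stim_amp;

    // 1) gates: exponential Euler at V_n; 2) assemble conductances
    for (int i = 0; i < nc; ++i) {
      double pos = (V[i] - vmin) * dv_inv;
      double gtot = 0.0, ge = 0.0;
      for (int k = 0; k < nch; ++k) {
        double act = 1.0;
        int gm = im[k];
        if (gm >= 0) {
          double xinf, afac;
          lerp2(gt[gm], pos, ntab - 1, xinf, afac);
          double x = xinf + (gates[gm * nc + i] - xinf) * afac;
          gates[gm * nc + i] = x;
          act = ipow(x, pexp[k]);
        }
        int gh = ih[k];
        if (gh >= 0) {
          double xinf, afac;
          lerp2(gt[gh], pos, ntab - 1, xinf, afac);
          double x = xinf + (gates[gh * nc + i] - xinf) * afac;
          gates[gh * nc + i] = x;
          if (qexp[k] > 0) act *= ipow(x, qexp[k]);
        }
        double g = gbar[k] * act;
        double e = (k == ina) ? ena[i] : erev[k];
        gtot += g;
        ge += g * e;
        if (k == ina) gna[i] = g;
      }
      // Crank-Nicolson: membrane conductance and diffusion split evenly
      // between the old and new time levels (second-order in dt)
      diag[i] = cdt + 0.5 * (gtot + 2.0 * gc);
      rhs[i] = (cdt - 0.5 * gtot) * V[i] + ge - ipump[i];
    }
    diag[0] -= 0.5 * gc; // sealed ends: single neighbour
    diag[nc - 1] -= 0.5 * gc;
    // explicit half of the diffusion operator
    rhs[0] += 0.5 * gc * (V[1] - V[0]);
    for (int i = 1; i < nc - 1; ++i)
      rhs[i] += 0.5 * gc * (V[i + 1] - 2.0 * V[i] + V[i - 1]);
    rhs[nc - 1] += 0.5 * gc * (V[nc - 2] - V[nc - 1]);
    rhs[stim_comp] += istim;

    // 3) Thomas solve: (diag) V - gch V(i-1) - gch V(i+1) = rhs
    const double gch = 0.5 * gc;
    cp[0] = -gch / diag[0];
    dp[0] = rhs[0] / diag[0];
    for (int i = 1; i < nc; ++i) {
      double m = diag[i] + gch * cp[i - 1];
      cp[i] = -gch / m;
      dp[i] = (rhs[i] + gch * dp[i - 1]) / m;
    }
    V[nc - 1] = dp[nc - 1];
    for (int i = nc - 2; i >= 0; --i) V[i] = dp[i] - cp[i] * V[i + 1];

    if (V[s1] > 200.0 || V[s1] < -200.0 || !std::isfinite(V[s1]))
      stop("numerical blow-up at t = %.3f ms (|V| > 200 mV at compartment %d)",
           t0 + (n + 1) * dt, s1 + 1);

    // 4) sodium balance (dynamic pump only)
    if (pump_mode == 1) {
      for (int i = 0; i < nc; ++i) {
        double ina_d = gna[i] * (V[i] - ena[i]);
        na[i] += dt * (-(ina_d + 3.0 * ipump[i])) * na_conv;
      }
      if ((n + 1) % slow_stride == 0) {
        for (int i = 0; i < nc; ++i) {
          ipump[i] = imax / (1.0 + std::exp((na_half - na[i]) / na_s));
          ena[i] = ena_scale * 58.0 * std::log10(na_out / na[i]);
        }
      }
    }
    sum_ina += gna[s1] * (V[s1] - ((ina >= 0) ? ena[s1] : 0.0));
    sum_ipump += ipump[s1];

    // 5) site-1 trough/peak gate snapshots
    {
      double v1 = V[s1];
      if (!det1.in_spike) {
        if (v1 <= det1.min_v) // new running minimum: snapshot gates
          for (int g = 0; g < ngate; ++g) cur_gtrough[g] = gates[g * nc + s1];
      } else if (v1 > cur_pk_v) {
        cur_pk_v = v1;
        for (int g = 0; g < ngate; ++g) cur_gpeak[g] = gates[g * nc + s1];
      }
      bool crossed = det1.step(n, v1);
      if (crossed) {
        cur_pk_v = v1;
        for (int g = 0; g < ngate; ++g) cur_gpeak[g] = gates[g * nc + s1];
        sp_ena.push_back(ena[s1]);
        sp_na.push_back(na[s1]);
        for (int g = 0; g < ngate; ++g)
          sp_gates_trough.push_back(cur_gtrough[g]);
      }
      if (s1_in_spike_prev && !det1.in_spike) // spike finalized this step
        for (int g = 0; g < ngate; ++g) sp_gates_peak.push_back(cur_gpeak[g]);
      s1_in_spike_prev = det1.in_spike;
    }
    det2.step(n, V[s2]);

    if (trace_stride > 0 && (n + 1) % trace_stride == 0) {
      tr_t.push_back((n + 1) * dt);
      tr_v1.push_back(V[s1]);
      tr_v2.push_back(V[s2]);
    }
    if (sample_stride > 0 && (n + 1) % sample_stride == 0) {
      smp_t.push_back((n + 1) * dt);
      smp_ipump.push_back(ipump[s1]);
      smp_na.push_back(na[s1]);
    }
  }

  // package spikes (only complete spikes have peak snapshots)
  size_t nsp1 = det1.t_cross.size();
  size_t nsp_complete = sp_gates_peak.size() / std::max(1, ngate);
  NumericMatrix gpk(std::min(nsp1, nsp_complete), ngate);
  NumericMatrix gtr(nsp1, ngate);
  for (size_t r = 0; r < (size_t)gpk.nrow(); ++r)
    for (int g = 0; g < ngate; ++g) gpk(r, g) = sp_gates_peak[r * ngate + g];
  for (size_t r = 0; r < nsp1; ++r)
    for (int g = 0; g < ngate; ++g) gtr(r, g) = sp_gates_trough[r * ngate + g];

  NumericMatrix Gout(nc, ngate);
  std::copy(gates.begin(), gates.end(), Gout.begin());

  List spikes1 = List::create(
      _["t_cross"] = NumericVector(det1.t_cross.begin(), det1.t_cross.end()),
      _["v_trough"] = NumericVector(det1.v_trough.begin(), det1.v_trough.end()),
      _["v_peak"] = NumericVector(det1.v_peak.begin(), det1.v_peak.end()),
      _["t_peak"] = NumericVector(det1.t_peak.begin(), det1.t_peak.end()),
      _["e_na"] = NumericVector(sp_ena.begin(), sp_ena.end()),
      _["na_in"] = NumericVector(sp_na.begin(), sp_na.end()),
      _["gates_peak"] = gpk, _["gates_trough"] = gtr);
  List spikes2 = List::create(
      _["t_cross"] = NumericVector(det2.t_cross.begin(), det2.t_cross.end()),
      _["t_peak"] = NumericVector(det2.t_peak.begin(), det2.t_peak.end()));

  // all reported times are local to this integration segment, matching the
  // stimulus-train time base; state$t_ms carries the accumulated clock
  return List::create(
      _["spikes1"] = spikes1, _["spikes2"] = spikes2,
      _["trace"] = List::create(_["t_ms"] = tr_t, _["v1"] = tr_v1,
                                _["v2"] = tr_v2),
      _["samples"] = List::create(_["t_ms"] = smp_t, _["ipump"] = smp_ipump,
                                  _["na_in"] = smp_na),
      _["mean_ina"] = sum_ina / n_steps,
      _["mean_ipump"] = sum_ipump / n_steps,
      _["state"] = List::create(_["v"] = NumericVector(V.begin(), V.end()),
                                _["gates"] = Gout,
                                _["na_in"] = NumericVector(na.begin(), na.end()),
                                _["t_ms"] = t0 + n_steps * dt));
}
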