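// Time-stepping core for the coupled cable / ion-concentration system.
//
// Scheme: backward Euler for the voltage on the tree (Hines-ordered
// elimination), exact exponential update for HH gates at frozen V, and
// first-order operator splitting for the concentration states (membrane
// fluxes then explicit conservative longitudinal diffusion). Concentration
// time scales are seconds, so the splitting error at dt ~ 0.025 ms is
// negligible relative to the voltage discretisation error.
//
// Units: um, ms, mV, mM, mA/cm^2, S/cm^2, uF/cm^2, nA, nS, mol/cm^2.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double FARADAY = 96485.33212;
static const double GAS_R = 8.31446262;
static const double RATE_PER_NA_UM3 = 1e6 / FARADAY; // mM um^3 / (nA ms)
static const double MOLFLUX_TO_MA = 1e6;             // mol cm^-2 ms^-1 -> mA/cm^2

struct Gate {
  double expo, vh, k, tau_min, tau_amp, vt, ka, kb;
  double xinf(double V) const { return 1.0 / (1.0 + std::exp(-(V - vh) / k)); }
  double tau(double V) const {
    double t = tau_min;
    if (tau_amp > 0)
      t += tau_amp / (std::exp((V - vt) / ka) + std::exp(-(V - vt) / kb));
    return t;
  }
};

struct Channel {
  int ion;      // 0 Na, 1 K, 2 Ca, 3 nonspecific
  int driving;  // 0 nernst_dynamic, 1 fixed, 2 ghk
  double E_fix;
  std::vector<double> gbar;        // per segment
  std::vector<Gate> gates;
  std::vector<double> x;           // state, n_seg * n_gates
};

static double ghk(double V, double Ci, double Co, double z, double rtf) {
  double xi = z * V / rtf;
  double ci = Ci * 1e-6, co = Co * 1e-6; // mM -> mol/cm^3
  double frac;
  if (std::fabs(xi) < 1e-6)
    frac = ci - co + (ci + co) * xi / 2.0;
  else
    frac = xi * (ci - co * std::exp(-xi)) / (1.0 - std::exp(-xi));
  return 1e3 * z * FARADAY * frac; // per unit permeability (cm/s)
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List model, List stim, List control) {
  // ---- geometry ----
  const IntegerVector parent = model["parent"]; // 0-based, -1 root
  const NumericVector area = model["area"];     // um^2
  const NumericVector vol = model["volume"];    // um^3
  const NumericVector gax = model["g_axial"];   // uS to parent
  const NumericVector cm = model["cm"];         // uF/cm^2 per segment
  const int n = parent.size();

  // ---- global parameters ----
  const double T_K = model["T_K"];
  const double rtf = 1000.0 * GAS_R * T_K / FARADAY; // mV
  const double Na_o = model["Na_o"], Ca_o = model["Ca_o"];
  const double E_K = model["E_K"];

  // ---- channels ----
  List chl = model["channels"];
  std::vector<Channel> channels(chl.size());
  for (int c = 0; c < chl.size(); ++c) {
    List one = chl[c];
    Channel &ch = channels[c];
    ch.ion = one["ion"];
    ch.driving = one["driving"];
    ch.E_fix = one["E_fix"];
    NumericVector gb = one["gbar"];
    ch.gbar.assign(gb.begin(), gb.end());
    NumericMatrix gp = one["gates"]; // rows: gates, cols: 8 params
    for (int g = 0; g < gp.nrow(); ++g) {
      Gate gt = {gp(g, 0), gp(g, 1), gp(g, 2), gp(g, 3),
                 gp(g, 4), gp(g, 5), gp(g, 6), gp(g, 7)};
      ch.gates.push_back(gt);
    }
    ch.x.assign((size_t)n * ch.gates.size(), 0.0);
  }

  // ---- Na pump ----
  List napump = model["na_pump"];
  const double nk1 = napump["k1"], nk2 = napump["k2"], nk3 = napump["k3"],
               nk4 = napump["k4"];
  const NumericVector narho = napump["density"];
  const int pump_kinetic = napump["kinetic"];

  // ---- Ca pump / NCX / buffer ----
  List capump = model["ca_pump"];
  const double ck1 = capump["k1"], ck2 = capump["k2"], ck3 = capump["k3"],
               ck4 = capump["k4"];
  const NumericVector carho = capump["density"];
  List ncx = model["ncx"];
  const NumericVector ncx_imax = ncx["I_max"];
  const double ncx_gamma = ncx["gamma"], ncx_kmna = ncx["km_Na"],
               ncx_kmca = ncx["km_Ca"], ncx_ksat = ncx["k_sat"];
  const int ncx_electro = ncx["electrogenic"];
  List buf = model["buffer"];
  const double buf_total = buf["total_buffer"], buf_kon = buf["k_on"],
               buf_koff = buf["k_off"];

  // ---- diffusion ----
  const NumericVector D_na = model["D_Na"]; // effective, per segment
  const int ca_diff = model["Ca_diffusible"];
  const double D_ca = model["D_Ca"];

  // ---- initial state ----
  NumericVector V = clone(as<NumericVector>(model["V0"]));
  NumericVector Na = clone(as<NumericVector>(model["Na0"]));
  NumericVector Ca = clone(as<NumericVector>(model["Ca0"]));
  const int freeze_na = model["freeze_na"];

  // gates start at steady state for V0
  for (auto &ch : channels)
    for (int i = 0; i < n; ++i)
      for (size_t g = 0; g < ch.gates.size(); ++g)
        ch.x[i * ch.gates.size() + g] = ch.gates[g].xinf(V[i]);

  // buffer bound state at equilibrium with Ca0
  std::vector<double> bound(n, 0.0);
  if (buf_total > 0 && buf_kon > 0)
    for (int i = 0; i < n; ++i)
      bound[i] = buf_total * Ca[i] / (buf_koff / buf_kon + Ca[i]);

  // kinetic pump occupancy at equilibrium with Na0
  std::vector<double> occ(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double a = nk1 * std::pow(Na[i], 3) + nk4 * std::pow(Na_o, 3);
    double ab = a + nk2 + nk3;
    occ[i] = (ab > 0) ? narho[i] * a / ab : 0.0;
  }

  // ---- stimuli ----
  const NumericVector p_on = stim["pulse_on"], p_off = stim["pulse_off"],
                      p_amp = stim["pulse_amp"];
  const IntegerVector p_seg = stim["pulse_seg"];
  // synapse instances
  const IntegerVector s_seg = stim["syn_seg"];
  const NumericVector s_tauon = stim["syn_tau_on"], s_tauoff = stim["syn_tau_off"],
                      s_erev = stim["syn_E_rev"], s_nafrac = stim["syn_na_frac"],
                      s_norm = stim["syn_norm"];
  const int n_syn = s_seg.size();
  // events, sorted by time
  const IntegerVector e_inst = stim["ev_inst"];
  const NumericVector e_time = stim["ev_time"], e_w = stim["ev_weight"];
  // voltage clamp
  const int clamp_seg = stim["clamp_seg"]; // -1 = none
  const NumericVector cl_t = stim["clamp_t"], cl_v = stim["clamp_v"];

  // ---- control ----
  const double dt = control["dt"];
  const int n_steps = control["n_steps"];
  const int rec_every = control["record_every"];
  const int detect_seg = control["detect_seg"];
  const double spike_thresh = control["spike_threshold"];

  // ---- precomputed axial coupling (density units) ----
  // row i gets  c_par[i] * (V_parent - V_i),  c_par in S/cm^2
  std::vector<double> c_par(n, 0.0);
  for (int i = 0; i < n; ++i)
    if (parent[i] >= 0) c_par[i] = 100.0 * gax[i] / area[i];

  // diffusion coefficients per edge (amount flux per mM difference)
  std::vector<double> dif_na(n, 0.0), dif_ca(n, 0.0), dx_edge(n, 0.0),
      across(n, 0.0);
  {
    NumericVector segL = model["length"];
    NumericVector cross = model["cross_section"];
    for (int i = 0; i < n; ++i) {
      int j = parent[i];
      if (j < 0) continue;
      dx_edge[i] = (segL[i] + segL[j]) / 2.0;
      across[i] = std::min(cross[i], cross[j]);
      dif_na[i] = 0.5 * (D_na[i] + D_na[j]) * across[i] / dx_edge[i];
      dif_ca[i] = D_ca * across[i] / dx_edge[i];
    }
  }

  // ---- recording buffers ----
  const int n_rec = n_steps / rec_every + 1;
  NumericVector t_rec(n_rec);
  NumericMatrix V_rec(n_rec, n), Na_rec(n_rec, n), Ca_rec(n_rec, n),
      Ip_rec(n_rec, n);
  NumericVector cum_ina_rec(n_rec), cum_pump_rec(n_rec), iclamp_rec(n_rec),
      cum_clamp_rec(n_rec);
  std::vector<double> spike_times;

  double cum_ina = 0.0;   // nA ms, net Na current excluding the pump
  double cum_pump = 0.0;  // nA ms, net Na-pump charge
  double cum_clamp = 0.0; // nA ms
  double last_spike = -1e9;
  bool above = V[detect_seg] >= spike_thresh;

  // synapse state
  std::vector<double> synA(n_syn, 0.0), synB(n_syn, 0.0);
  std::vector<double> dec_on(n_syn), dec_off(n_syn);
  for (int s = 0; s < n_syn; ++s) {
    dec_on[s] = std::exp(-dt / s_tauon[s]);
    dec_off[s] = std::exp(-dt / s_tauoff[s]);
  }
  int ev_ptr = 0;
  int cl_ptr = 0;

  // scratch
  std::vector<double> G(n), GE(n), Jc(n), d(n), r(n), b_par(n),
      Ipump(n), Jna(n), Jca(n), Jsyn_na(n);

  auto record = [&](int row, double t, double iclamp) {
    t_rec[row] = t;
    for (int i = 0; i < n; ++i) {
      V_rec(row, i) = V[i];
      Na_rec(row, i) = Na[i];
      Ca_rec(row, i) = Ca[i];
      Ip_rec(row, i) = Ipump[i];
    }
    cum_ina_rec[row] = cum_ina;
    cum_pump_rec[row] = cum_pump;
    iclamp_rec[row] = iclamp;
    cum_clamp_rec[row] = cum_clamp;
  };

  // initial pump current (for the t=0 record)
  for (int i = 0; i < n; ++i) {
    double ci3 = std::pow(Na[i], 3), co3 = std::pow(Na_o, 3);
    double den = nk1 * ci3 + nk4 * co3 + nk2 + nk3;
    Ipump[i] = (narho[i] > 0 && den > 0)
                   ? (FARADAY / 3.0) * narho[i] *
                         (nk1 * nk3 * ci3 - nk2 * nk4 * co3) / den *
                         MOLFLUX_TO_MA
                   : 0.0;
  }
  record(0, 0.0, 0.0);
  int rec_row = 1;

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;

    // --- synaptic events due in [t, t+dt) fire at the start of the step ---
    while (ev_ptr < e_inst.size() && e_time[ev_ptr] < t + dt) {
      int s = e_inst[ev_ptr];
      double w = e_w[ev_ptr] * s_norm[s];
      synA[s] += w;
      synB[s] += w;
      ++ev_ptr;
    }

    // --- gate update at frozen V ---
    for (auto &ch : channels) {
      size_t ng = ch.gates.size();
      for (size_t g = 0; g < ng; ++g) {
        const Gate &gt = ch.gates[g];
        for (int i = 0; i < n; ++i) {
          if (ch.gbar[i] <= 0) continue;
          double xi = gt.xinf(V[i]);
          double tv = gt.tau(V[i]);
          double &x = ch.x[i * ng + g];
          x = xi + (x - xi) * std::exp(-dt / tv);
        }
      }
    }

    // --- assemble linear membrane terms ---
    for (int i = 0; i < n; ++i) {
      G[i] = 0.0; GE[i] = 0.0; Jc[i] = 0.0; Jna[i] = 0.0; Jca[i] = 0.0;
      Jsyn_na[i] = 0.0;
    }
    for (auto &ch : channels) {
      size_t ng = ch.gates.size();
      for (int i = 0; i < n; ++i) {
        if (ch.gbar[i] <= 0) continue;
        double open = 1.0;
        for (size_t g = 0; g < ng; ++g)
          open *= std::pow(ch.x[i * ng + g], ch.gates[g].expo);
        double gd = ch.gbar[i] * open;
        if (ch.driving == 2) { // ghk, explicit at V_old
          double z = (ch.ion == 2) ? 2.0 : 1.0;
          double Ci = (ch.ion == 2) ? Ca[i] : Na[i];
          double Co = (ch.ion == 2) ? Ca_o : Na_o;
          Jc[i] += gd * ghk(V[i], Ci, Co, z, rtf);
        } else {
          double E = ch.E_fix;
          if (ch.driving == 0 && ch.ion == 0) E = rtf * std::log(Na_o / Na[i]);
          G[i] += gd;
          GE[i] += gd * E;
        }
      }
    }

    // synapses: conductance with dynamic-E_Na split
    for (int s = 0; s < n_syn; ++s) {
      double g_nS = synB[s] - synA[s];
      if (g_nS <= 1e-12) continue;
      int i = s_seg[s];
      double gd = 0.1 * g_nS / area[i]; // S/cm^2
      double ena = rtf * std::log(Na_o / Na[i]);
      double gna = gd * s_nafrac[s], gk = gd - gna;
      G[i] += gd;
      GE[i] += gna * ena + gk * E_K;
    }

    // Na pump (steady-state or kinetic)
    for (int i = 0; i < n; ++i) {
      double ci3 = std::pow(Na[i], 3), co3 = std::pow(Na_o, 3);
      if (narho[i] <= 0) {
        Ipump[i] = 0.0;
      } else if (pump_kinetic) {
        double a = nk1 * ci3 + nk4 * co3, b = nk2 + nk3;
        if (a + b > 0) {
          double pinf = narho[i] * a / (a + b);
          occ[i] = pinf + (occ[i] - pinf) * std::exp(-(a + b) * dt);
        }
        Ipump[i] = (FARADAY / 3.0) *
                   (nk1 * (narho[i] - occ[i]) * ci3 - nk2 * occ[i]) *
                   MOLFLUX_TO_MA;
      } else {
        double den = nk1 * ci3 + nk4 * co3 + nk2 + nk3;
        Ipump[i] = (den > 0) ? (FARADAY / 3.0) * narho[i] *
                                   (nk1 * nk3 * ci3 - nk2 * nk4 * co3) /
                                   den * MOLFLUX_TO_MA
                             : 0.0;
      }
      Jc[i] += Ipump[i];
    }

    // NCX (explicit at V_old)
    std::vector<double> Incx(n, 0.0);
    for (int i = 0; i < n; ++i) {
      if (ncx_imax[i] <= 0) continue;
      double th = V[i] / rtf;
      double e1 = std::exp(ncx_gamma * th), e2 = std::exp((ncx_gamma - 1) * th);
      double num = std::pow(Na[i], 3) * Ca_o * e1 -
                   std::pow(Na_o, 3) * Ca[i] * e2;
      double den = (std::pow(ncx_kmna, 3) + std::pow(Na_o, 3)) *
                   (ncx_kmca + Ca_o) * (1.0 + ncx_ksat * e2);
      Incx[i] = ncx_imax[i] * num / den;
      if (ncx_electro) Jc[i] += Incx[i];
    }

    // injected currents
    std::vector<double> Jinj(n, 0.0);
    for (int p = 0; p < p_on.size(); ++p)
      if (p_on[p] <= t && t < p_off[p])
        Jinj[p_seg[p]] += 100.0 * p_amp[p] / area[p_seg[p]];

    // clamp command
    double vcmd = 0.0;
    bool clamped = clamp_seg >= 0;
    if (clamped) {
      while (cl_ptr + 1 < cl_t.size() && cl_t[cl_ptr + 1] <= t) ++cl_ptr;
      vcmd = cl_v[cl_ptr];
    }

    // --- Hines solve: gamma (V' - V) = -(G V' - GE) - Jc + Jax(V') + Jinj ---
    for (int i = 0; i < n; ++i) {
      double gam = cm[i] / (1000.0 * dt);
      d[i] = gam + G[i];
      r[i] = gam * V[i] + GE[i] - Jc[i] + Jinj[i];
      if (parent[i] >= 0) d[i] += c_par[i];
    }
    // children add to the parent diagonal
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      b_par[i] = 100.0 * gax[i] / area[p]; // coefficient of V_i in row p
      d[p] += b_par[i];
    }
    if (clamped) { d[clamp_seg] = 1.0; r[clamp_seg] = vcmd; }
    // eliminate children (rows ordered parents-first)
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      if (p == clamp_seg && clamped) {
        // clamped parent row is fixed; nothing propagates into it
      } else if (i == clamp_seg && clamped) {
        r[p] += b_par[i] * vcmd; // known child value
      } else {
        double f = b_par[i] / d[i];
        d[p] -= f * c_par[i];
        r[p] += f * r[i]; // note signs: off-diagonals are -c_par, -b_par
      }
    }
    std::vector<double> Vn(n);
    Vn[0] = (clamped && clamp_seg == 0) ? vcmd : r[0] / d[0];
    for (int i = 1; i < n; ++i) {
      if (clamped && i == clamp_seg) { Vn[i] = vcmd; continue; }
      Vn[i] = (r[i] + c_par[i] * Vn[parent[i]]) / d[i];
    }

    // clamp current (nA): residual of the clamped row
    double iclamp = 0.0;
    if (clamped) {
      int i = clamp_seg;
      double gam = cm[i] / (1000.0 * dt);
      double jax = 0.0;
      if (parent[i] >= 0) jax += c_par[i] * (Vn[parent[i]] - Vn[i]);
      for (int k2 = 0; k2 < n; ++k2)
        if (parent[k2] == i)
          jax += 100.0 * gax[k2] / area[i] * (Vn[k2] - Vn[i]);
      double dens = gam * (Vn[i] - V[i]) + G[i] * Vn[i] - GE[i] + Jc[i] -
                    jax - Jinj[i];
      iclamp = dens * area[i] * 0.01;
      cum_clamp += iclamp * dt;
    }

    // --- ionic fluxes at V_new ---
    for (auto &ch : channels) {
      size_t ng = ch.gates.size();
      for (int i = 0; i < n; ++i) {
        if (ch.gbar[i] <= 0) continue;
        double open = 1.0;
        for (size_t g = 0; g < ng; ++g)
          open *= std::pow(ch.x[i * ng + g], ch.gates[g].expo);
        double gd = ch.gbar[i] * open;
        if (ch.driving == 2) {
          double z = (ch.ion == 2) ? 2.0 : 1.0;
          double Ci = (ch.ion == 2) ? Ca[i] : Na[i];
          double Co = (ch.ion == 2) ? Ca_o : Na_o;
          double J = gd * ghk(Vn[i], Ci, Co, z, rtf);
          if (ch.ion == 2) Jca[i] += J; else Jna[i] += J;
        } else if (ch.ion == 0) {
          double ena = rtf * std::log(Na_o / Na[i]);
          Jna[i] += gd * (Vn[i] - ena);
        }
      }
    }
    for (int s = 0; s < n_syn; ++s) {
      double g_nS = synB[s] - synA[s];
      if (g_nS <= 1e-12) continue;
      int i = s_seg[s];
      double gna = 0.1 * g_nS * s_nafrac[s] / area[i];
      double ena = rtf * std::log(Na_o / Na[i]);
      Jsyn_na[i] += gna * (Vn[i] - ena);
    }

    // --- concentration updates ---
    double step_ina = 0.0, step_pump = 0.0;
    for (int i = 0; i < n; ++i) {
      double Ina_nA = (Jna[i] + Jsyn_na[i] + 3.0 * Incx[i]) * area[i] * 0.01;
      double Ipump_nA = Ipump[i] * area[i] * 0.01;
      step_ina += Ina_nA;
      step_pump += Ipump_nA;
      if (!freeze_na) {
        double dna = -(Ina_nA + 3.0 * Ipump_nA) * RATE_PER_NA_UM3 / vol[i];
        Na[i] += dna * dt;
        if (Na[i] < 1e-6) Na[i] = 1e-6;
      }
      // Ca: channels (z=2), pump (2 charges per ion), NCX (1 charge per ion)
      double ci = Ca[i];
      double cden = ck1 * ci + ck4 * Ca_o + ck2 + ck3;
      double Icap = (carho[i] > 0 && cden > 0)
                        ? (2.0 * FARADAY) * carho[i] *
                              (ck1 * ck3 * ci - ck2 * ck4 * Ca_o) / cden *
                              MOLFLUX_TO_MA
                        : 0.0;
      double rate = (-Jca[i] / 2.0 - Icap / 2.0 + Incx[i]) * area[i] * 0.01 *
                    RATE_PER_NA_UM3 / vol[i];
      if (buf_total > 0) {
        double flux = buf_kon * ci * (buf_total - bound[i]) -
                      buf_koff * bound[i];
        rate -= flux;
        bound[i] += flux * dt;
        if (bound[i] < 0) bound[i] = 0;
        if (bound[i] > buf_total) bound[i] = buf_total;
      }
      Ca[i] += rate * dt;
      if (Ca[i] < 1e-9) Ca[i] = 1e-9;
    }
    cum_ina += step_ina * dt;
    cum_pump += step_pump * dt;

    // --- longitudinal diffusion (conservative, explicit) ---
    if (!freeze_na) {
      std::vector<double> amt(n);
      for (int i = 0; i < n; ++i) amt[i] = Na[i] * vol[i];
      for (int i = 1; i < n; ++i) {
        int j = parent[i];
        double J = dif_na[i] * (Na[j] - Na[i]) * dt;
        amt[i] += J;
        amt[j] -= J;
      }
      for (int i = 0; i < n; ++i) Na[i] = amt[i] / vol[i];
    }
    if (ca_diff) {
      std::vector<double> amt(n);
      for (int i = 0; i < n; ++i) amt[i] = Ca[i] * vol[i];
      for (int i = 1; i < n; ++i) {
        int j = parent[i];
        double J = dif_ca[i] * (Ca[j] - Ca[i]) * dt;
        amt[i] += J;
        amt[j] -= J;
      }
      for (int i = 0; i < n; ++i) Ca[i] = amt[i] / vol[i];
    }

    // --- spike detection ---
    double vdet = Vn[detect_seg];
    if (!above && vdet >= spike_thresh && t + dt - last_spike >= 1.0) {
      spike_times.push_back(t + dt);
      last_spike = t + dt;
      above = true;
    } else if (above && vdet < spike_thresh) {
      above = false;
    }

    for (int i = 0; i < n; ++i) V[i] = Vn[i];

    // decay synaptic state to the end of the step
    for (int s = 0; s < n_syn; ++s) {
      synA[s] *= dec_on[s];
      synB[s] *= dec_off[s];
    }

    if (!std::isfinite(V[0]) || !std::isfinite(Na[0]))
      stop("solver divergence (non-finite state) at t = %f ms", t);

    if ((step + 1) % rec_every == 0 && rec_row < n_rec)
      record(rec_row++, t + dt, iclamp);
  }

  return List::create(
      _["t"] = t_rec, _["V"] = V_rec, _["Na"] = Na_rec, _["Ca"] = Ca_rec,
      _["I_pump"] = Ip_rec, _["cum_I_Na"] = cum_ina_rec,
      _["cum_I_pump"] = cum_pump_rec, _["I_clamp"] = iclamp_rec,
      _["cum_I_clamp"] = cum_clamp_rec,
      _["spike_times"] = NumericVector(spike_times.begin(), spike_times.end()));
}
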