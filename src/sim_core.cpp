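#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// x / (exp(x/den) - 1) with the removable singularity at x = 0 evaluated
// by its limit (den - x/2 to first order).
static inline double vtrap(double x, double den) {
  double r = x / den;
  if (std::fabs(r) < 1e-7) return den * (1.0 - 0.5 * r);
  return x / (std::exp(r) - 1.0);
}

struct GateRates { double aN, bN, aM, bM, aH, bH; };

// Gating rates in ms^-1.  V is the classic displacement coordinate
// V = Vrp - Vm (depolarisation negative).  The modified variant replaces
// alpha_M's (V+25) numerator/exponent with (V+10), which lowers the firing
// threshold to the resting potential.
static inline GateRates hh_rates(double Vm, double Vrp, bool modified) {
  double V = Vrp - Vm;
  GateRates g;
  g.aN = 0.01 * vtrap(V + 10.0, 10.0);
  g.bN = 0.125 * std::exp(V / 80.0);
  g.aM = modified ? 0.1 * vtrap(V + 10.0, 10.0)
                  : 0.1 * vtrap(V + 25.0, 10.0);
  g.bM = 4.0 * std::exp(V / 18.0);
  g.aH = 0.07 * std::exp(V / 20.0);
  g.bH = 1.0 / (std::exp((V + 30.0) / 10.0) + 1.0);
  return g;
}

struct HHParams {
  double gK, gNa, EK, ENa, El, Rl, Cm, Vrp, coeff;
  bool modified;
};

struct HHState { double V, N, M, H; };

static inline double gate_update(double x, double a, double b,
                                 double coeff, double dt) {
  double s = a + b;
  if (s <= 0.0) return x;
  double xinf = a / s;
  return xinf + (x - xinf) * std::exp(-coeff * s * dt);
}

// One integration step: Rush-Larsen (exact exponential) update of the
// gating variables followed by an exponential-Euler update of Vm.  Both
// are unconditionally stable, which matters because the gating rate
// coefficient can make the gate dynamics far faster than the membrane.
static inline void hh_step(HHState &s, double Im, const HHParams &p,
                           double dt) {
  GateRates r = hh_rates(s.V, p.Vrp, p.modified);
  s.N = gate_update(s.N, r.aN, r.bN, p.coeff, dt);
  s.M = gate_update(s.M, r.aM, r.bM, p.coeff, dt);
  s.H = gate_update(s.H, r.aH, r.bH, p.coeff, dt);
  double gKn = p.gK * s.N * s.N * s.N * s.N;      // mS
  double gNam = p.gNa * s.M * s.M * s.M * s.H;    // mS
  double gl = 1.0 / p.Rl;                         // 1/kOhm = mS
  double gt = gKn + gNam + gl;
  double Vinf = (Im + gKn * p.EK + gNam * p.ENa + gl * p.El) / gt;
  s.V = Vinf + (s.V - Vinf) * std::exp(-gt * dt / p.Cm);
}

static inline HHState hh_rest(const HHParams &p) {
  GateRates r = hh_rates(p.Vrp, p.Vrp, p.modified);
  HHState s;
  s.V = p.Vrp;
  s.N = r.aN / (r.aN + r.bN);
  s.M = r.aM / (r.aM + r.bM);
  s.H = r.aH / (r.aH + r.bH);
  return s;
}

static HHParams hh_from_list(const List &ax) {
  HHParams p;
  p.gK = as<double>(ax["g_K"]);
  p.gNa = as<double>(ax["g_Na"]);
  p.EK = as<double>(ax["E_K"]);
  p.ENa = as<double>(ax["E_Na"]);
  p.El = as<double>(ax["E_l"]);
  p.Rl = as<double>(ax["R_l"]);
  p.Cm = as<double>(ax["C_m"]);
  p.Vrp = as<double>(ax["V_rp"]);
  p.coeff = as<double>(ax["rate_coefficient"]);
  p.modified = as<std::string>(ax["variant"]) == "modified";
  return p;
}

// ---------------------------------------------------------------------
// Passive dendrite ladder.  Units: uA, kOhm, uF, mV, ms (uA x kOhm = mV).
// ---------------------------------------------------------------------

struct DendParams { int n; double Cm, Req, Ra, Vth; };

static inline void dend_deriv(const std::vector<double> &v,
                              std::vector<double> &dv,
                              const DendParams &p, double is) {
  int n = p.n;
  for (int i = 0; i < n; ++i) {
    double cur = -(v[i] - p.Vth) / p.Req;
    if (i == 0) cur += is; else cur += (v[i - 1] - v[i]) / p.Ra;
    if (i < n - 1) cur += (v[i + 1] - v[i]) / p.Ra;
    dv[i] = cur / p.Cm;
  }
}

struct DendWork {
  std::vector<double> k1, k2, k3, k4, tmp;
  void resize(int n) {
    k1.resize(n); k2.resize(n); k3.resize(n); k4.resize(n); tmp.resize(n);
  }
};

// Classic RK4 step with the stimulus held constant over the step (the
// stimulus is a rectangular pulse train, so it is piecewise constant).
static inline void dend_step(std::vector<double> &v, const DendParams &p,
                             double is, double dt, DendWork &w) {
  int n = p.n;
  dend_deriv(v, w.k1, p, is);
  for (int i = 0; i < n; ++i) w.tmp[i] = v[i] + 0.5 * dt * w.k1[i];
  dend_deriv(w.tmp, w.k2, p, is);
  for (int i = 0; i < n; ++i) w.tmp[i] = v[i] + 0.5 * dt * w.k2[i];
  dend_deriv(w.tmp, w.k3, p, is);
  for (int i = 0; i < n; ++i) w.tmp[i] = v[i] + dt * w.k3[i];
  dend_deriv(w.tmp, w.k4, p, is);
  for (int i = 0; i < n; ++i)
    v[i] += dt / 6.0 * (w.k1[i] + 2.0 * w.k2[i] + 2.0 * w.k3[i] + w.k4[i]);
}

// Evaluate a rectangular pulse train at the step grid: returns a vector of
// the summed pulse current per step.  onset/width in ms, amp signed uA.
static std::vector<double> pulses_to_grid(const NumericMatrix &pulses,
                                          int nsteps, double dt) {
  std::vector<double> is(nsteps + 1, 0.0);
  for (int r = 0; r < pulses.nrow(); ++r) {
    double a = pulses(r, 2);
    int k0 = (int)std::ceil(pulses(r, 0) / dt - 1e-9);
    int k1 = (int)std::ceil((pulses(r, 0) + pulses(r, 1)) / dt - 1e-9);
    if (k0 < 0) k0 = 0;
    if (k1 > nsteps) k1 = nsteps;
    for (int k = k0; k < k1; ++k) is[k] += a;
  }
  return is;
}

// [[Rcpp::export]]
List cpp_simulate_dendrite(NumericMatrix pulses, List params,
                           double duration, double dt, int record_every) {
  DendParams p;
  p.n = as<int>(params["n_compartments"]);
  p.Cm = as<double>(params["C_m"]);
  p.Req = as<double>(params["R_EQ"]);
  p.Ra = as<double>(params["R_a"]);
  p.Vth = as<double>(params["V_TH"]);
  int nsteps = (int)std::round(duration / dt);
  std::vector<double> is = pulses_to_grid(pulses, nsteps, dt);
  std::vector<double> v(p.n, p.Vth);
  DendWork w; w.resize(p.n);
  int nrec = nsteps / record_every + 1;
  NumericMatrix vm(nrec, p.n);
  NumericVector tt(nrec);
  int ir = 0;
  for (int k = 0; k <= nsteps; ++k) {
    if (k % record_every == 0 && ir < nrec) {
      tt[ir] = k * dt;
      for (int i = 0; i < p.n; ++i) vm(ir, i) = v[i];
      ++ir;
    }
    if (k == nsteps) break;
    dend_step(v, p, is[k], dt, w);
    for (int i = 0; i < p.n; ++i)
      if (!std::isfinite(v[i]))
        stop("dendrite integration failure at t = %f ms", k * dt);
  }
  return List::create(_["time"] = tt, _["v_m"] = vm);
}

// ---------------------------------------------------------------------
// Single axon simulation driven by a sampled membrane current.
// ---------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_axon(NumericVector Im, List params, double dt,
                       int record_every, double spike_level) {
  HHParams p = hh_from_list(params);
  HHState s = hh_rest(p);
  int nsteps = Im.size();
  int nrec = nsteps / record_every + 1;
  NumericVector vv(nrec), tt(nrec), NN(nrec), MM(nrec), HH_(nrec);
  std::vector<double> spikes;
  int ir = 0;
  double Vprev = s.V;
  for (int k = 0; k <= nsteps; ++k) {
    if (k % record_every == 0 && ir < nrec) {
      tt[ir] = k * dt; vv[ir] = s.V;
      NN[ir] = s.N; MM[ir] = s.M; HH_[ir] = s.H;
      ++ir;
    }
    if (k == nsteps) break;
    Vprev = s.V;
    hh_step(s, Im[k], p, dt);
    if (!std::isfinite(s.V))
      stop("axon integration failure at t = %f ms", k * dt);
    if (Vprev < spike_level && s.V >= spike_level) {
      double f = (spike_level - Vprev) / (s.V - Vprev);
      spikes.push_back((k + f) * dt);
    }
  }
  return List::create(_["time"] = tt, _["V_m"] = vv,
                      _["N"] = NN, _["M"] = MM, _["H"] = HH_,
                      _["spikes"] = NumericVector(spikes.begin(), spikes.end()));
}

// ---------------------------------------------------------------------
// FitzHugh-Nagumo tonic unit.
// dv/dt = k (v - v^3/3 - w + I),  dw/dt = k eps (v + a - b w)
// ---------------------------------------------------------------------

struct FHNParams { double a, b, eps, k; };
struct FHNState { double v, w; };

static inline void fhn_step(FHNState &s, double I, const FHNParams &p,
                            double dt) {
  // Heun (explicit trapezoid); the oscillator is non-stiff at the ms scale.
  double dv1 = p.k * (s.v - s.v * s.v * s.v / 3.0 - s.w + I);
  double dw1 = p.k * p.eps * (s.v + p.a - p.b * s.w);
  double vp = s.v + dt * dv1, wp = s.w + dt * dw1;
  double dv2 = p.k * (vp - vp * vp * vp / 3.0 - wp + I);
  double dw2 = p.k * p.eps * (vp + p.a - p.b * wp);
  s.v += 0.5 * dt * (dv1 + dv2);
  s.w += 0.5 * dt * (dw1 + dw2);
}

// [[Rcpp::export]]
List cpp_simulate_fhn(NumericVector I, List params, double dt,
                      int record_every, double spike_level,
                      double v0, double w0) {
  FHNParams p;
  p.a = as<double>(params["a"]); p.b = as<double>(params["b"]);
  p.eps = as<double>(params["eps"]); p.k = as<double>(params["timescale"]);
  FHNState s; s.v = v0; s.w = w0;
  int nsteps = I.size();
  int nrec = nsteps / record_every + 1;
  NumericVector vv(nrec), ww(nrec), tt(nrec);
  std::vector<double> spikes;
  int ir = 0;
  for (int k = 0; k <= nsteps; ++k) {
    if (k % record_every == 0 && ir < nrec) {
      tt[ir] = k * dt; vv[ir] = s.v; ww[ir] = s.w; ++ir;
    }
    if (k == nsteps) break;
    double vprev = s.v;
    fhn_step(s, I[k], p, dt);
    if (vprev < spike_level && s.v >= spike_level) {
      double f = (spike_level - vprev) / (s.v - vprev);
      spikes.push_back((k + f) * dt);
    }
  }
  return List::create(_["time"] = tt, _["v"] = vv, _["w"] = ww,
                      _["spikes"] = NumericVector(spikes.begin(), spikes.end()));
}

// ---------------------------------------------------------------------
// Coupled circuit simulation.
//
// Every neuron owns a dendrite ladder plus either an HH axon (model 0
// basic, 1 modified) or an FHN oscillator (model 2).  Synaptic coupling:
// the postsynaptic current of connection c at time t is
//   sign * amp * [V_src(t - delay) > level_src],
// i.e. a rectangular pulse spanning the presynaptic spike's crossing of
// the detection level, shifted by the axonal delay (realised with a ring
// buffer of threshold states).
// ---------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_circuit(List neurons, IntegerMatrix conn,
                          NumericVector conn_amp, List drive_pulses,
                          double duration, double dt, int record_every) {
  int nn = neurons.size();
  int nc = conn.nrow();
  int nsteps = (int)std::round(duration / dt);

  std::vector<DendParams> dp(nn);
  std::vector<DendWork> dw(nn);
  std::vector<std::vector<double> > dv(nn);
  std::vector<int> model(nn);
  std::vector<HHParams> hp(nn);
  std::vector<HHState> hs(nn);
  std::vector<FHNParams> fp(nn);
  std::vector<FHNState> fs(nn);
  std::vector<double> gain_in(nn, 1.0), level(nn, 0.0);
  std::vector<double> fIb(nn, 0.0), fgden(nn, 0.0), fgint(nn, 0.0),
      fwinh(nn, 1.0), ftleak(nn, 0.0), acc(nn, 0.0);

  for (int i = 0; i < nn; ++i) {
    List nl = neurons[i];
    List den = nl["dendrite"];
    dp[i].n = as<int>(den["n_compartments"]);
    dp[i].Cm = as<double>(den["C_m"]);
    dp[i].Req = as<double>(den["R_EQ"]);
    dp[i].Ra = as<double>(den["R_a"]);
    dp[i].Vth = as<double>(den["V_TH"]);
    dw[i].resize(dp[i].n);
    dv[i].assign(dp[i].n, dp[i].Vth);
    std::string mdl = as<std::string>(nl["model"]);
    level[i] = as<double>(nl["detection_level"]);
    if (mdl == "fhn") {
      model[i] = 2;
      List f = nl["oscillator"];
      fp[i].a = as<double>(f["a"]); fp[i].b = as<double>(f["b"]);
      fp[i].eps = as<double>(f["eps"]);
      fp[i].k = as<double>(f["timescale"]);
      fIb[i] = as<double>(f["I_base"]);
      fgden[i] = as<double>(f["gain_dendrite"]);
      fgint[i] = as<double>(f["gain_integrator"]);
      fwinh[i] = as<double>(f["w_inhibitory"]);
      ftleak[i] = as<double>(f["tau_leak"]);
      fs[i].v = -1.2; fs[i].w = -0.62;
    } else {
      List ax = nl["axon"];
      hp[i] = hh_from_list(ax);
      model[i] = hp[i].modified ? 1 : 0;
      gain_in[i] = as<double>(ax["gain_in"]);
      hs[i] = hh_rest(hp[i]);
    }
  }

  // Connections: integer columns src, tgt (0-based), delay_steps;
  // conn_amp holds the signed pulse amplitude (uA) per connection.
  std::vector<int> csrc(nc), ctgt(nc), cdel(nc);
  std::vector<double> camp(nc);
  int maxdel = 1;
  for (int c = 0; c < nc; ++c) {
    csrc[c] = conn(c, 0); ctgt[c] = conn(c, 1);
    cdel[c] = conn(c, 2);
    camp[c] = conn_amp[c];
    if (cdel[c] + 1 > maxdel) maxdel = cdel[c] + 1;
  }
  std::vector<std::vector<char> > hist(nn, std::vector<char>(maxdel, 0));

  // External scripted drives: per neuron a pulse matrix (onset, width, amp)
  // converted to per-step step-change events.
  std::vector<std::vector<double> > drive(nn);
  for (int i = 0; i < nn; ++i) {
    NumericMatrix pm = drive_pulses[i];
    if (pm.nrow() > 0) drive[i] = pulses_to_grid(pm, nsteps, dt);
  }

  int nrec = nsteps / record_every + 1;
  NumericVector tt(nrec);
  NumericMatrix Vax(nrec, nn), Vden(nrec, nn), Acc(nrec, nn);
  std::vector<std::vector<double> > ups(nn), downs(nn);
  std::vector<double> outV(nn), outVprev(nn);
  for (int i = 0; i < nn; ++i)
    outV[i] = (model[i] == 2) ? fs[i].v : hs[i].V;

  int ir = 0;
  for (int k = 0; k <= nsteps; ++k) {
    if (k % record_every == 0 && ir < nrec) {
      tt[ir] = k * dt;
      for (int i = 0; i < nn; ++i) {
        Vax(ir, i) = outV[i];
        Vden(ir, i) = dv[i][dp[i].n - 1];
        Acc(ir, i) = acc[i];
      }
      ++ir;
    }
    if (k == nsteps) break;

    // Synaptic + drive current per neuron at time t_k.
    std::vector<double> is(nn, 0.0), isneg(nn, 0.0), ispos(nn, 0.0);
    for (int i = 0; i < nn; ++i)
      if (!drive[i].empty()) { is[i] += drive[i][k]; ispos[i] += drive[i][k]; }
    for (int c = 0; c < nc; ++c) {
      int kk = k - cdel[c];
      char on = (kk >= 0) ? hist[csrc[c]][kk % maxdel] : 0;
      if (on) {
        is[ctgt[c]] += camp[c];
        if (camp[c] > 0) ispos[ctgt[c]] += camp[c];
        else isneg[ctgt[c]] += camp[c];
      }
    }

    // Advance every neuron by dt.
    for (int i = 0; i < nn; ++i) {
      dend_step(dv[i], dp[i], is[i], dt, dw[i]);
      double vlast = dv[i][dp[i].n - 1];
      outVprev[i] = outV[i];
      if (model[i] == 2) {
        acc[i] += dt * (ispos[i] + fwinh[i] * isneg[i]);
        if (ftleak[i] > 0.0) acc[i] -= dt * acc[i] / ftleak[i];
        double I = fIb[i] + fgden[i] * (vlast - dp[i].Vth)
                 + fgint[i] * acc[i];
        fhn_step(fs[i], I, fp[i], dt);
        outV[i] = fs[i].v;
      } else {
        double Im = gain_in[i] * (vlast - dp[i].Vth) / dp[i].Ra;  // uA
        hh_step(hs[i], Im, hp[i], dt);
        outV[i] = hs[i].V;
      }
      if (!std::isfinite(outV[i]))
        stop("circuit integration failure: neuron %d at t = %f ms",
             i + 1, k * dt);
      // Crossings of the synaptic detection level.
      if (outVprev[i] < level[i] && outV[i] >= level[i]) {
        double f = (level[i] - outVprev[i]) / (outV[i] - outVprev[i]);
        ups[i].push_back((k + f) * dt);
      } else if (outVprev[i] >= level[i] && outV[i] < level[i]) {
        double f = (outVprev[i] - level[i]) / (outVprev[i] - outV[i]);
        downs[i].push_back((k + f) * dt);
      }
      hist[i][(k + 1) % maxdel] = (outV[i] >= level[i]) ? 1 : 0;
    }
  }

  List lups(nn), ldowns(nn);
  for (int i = 0; i < nn; ++i) {
    lups[i] = NumericVector(ups[i].begin(), ups[i].end());
    ldowns[i] = NumericVector(downs[i].begin(), downs[i].end());
  }
  return List::create(_["time"] = tt, _["V_axon"] = Vax,
                      _["V_dendrite"] = Vden, _["acc"] = Acc,
                      _["ups"] = lups, _["downs"] = ldowns);
}

// ---------------------------------------------------------------------
// Muscle-fiber oculomotor plant.
//
// SI units throughout (m, N, s).  State: x = r * theta (arc length), xd,
// and the element stretches y of one agonist and one antagonist column
// (all columns are identical, so net torque is n_col times one column).
// Column tension T_i is eliminated algebraically from the series
// constraint sum_j ydot_j = xdot.
// ---------------------------------------------------------------------

struct PlantPar {
  double Kse, B2, Klt, B1, Jp, Bp, Kp, r;
  int m, ncol;
};

struct PlantState {
  double x, xd;
  std::vector<double> ya, yt;  // agonist / antagonist, length m+2
};

// Forcing per fiber (agonist Fa[j], antagonist Ft[j], j = 0..m-1, N).
static void plant_deriv(const PlantState &s, const std::vector<double> &Fa,
                        const std::vector<double> &Ft, const PlantPar &p,
                        PlantState &d, double &Tag, double &Tant) {
  int m = p.m;
  double den = 2.0 / p.B2 + m / p.B1;
  // Agonist column tension.
  double sa = (p.Kse / p.B2) * (s.ya[0] + s.ya[m + 1]);
  for (int j = 0; j < m; ++j) sa += (p.Klt * s.ya[j + 1] - Fa[j]) / p.B1;
  double Ta = -(s.xd + sa) / den;
  // Antagonist column tension.
  double st = (p.Kse / p.B2) * (s.yt[0] + s.yt[m + 1]);
  for (int j = 0; j < m; ++j) st += (p.Klt * s.yt[j + 1] + Ft[j]) / p.B1;
  double Tt = (s.xd + st) / den;
  Tag = p.ncol * Ta;
  Tant = p.ncol * Tt;

  d.ya[0] = -(Ta + p.Kse * s.ya[0]) / p.B2;
  d.ya[m + 1] = -(Ta + p.Kse * s.ya[m + 1]) / p.B2;
  for (int j = 0; j < m; ++j)
    d.ya[j + 1] = (-Ta - p.Klt * s.ya[j + 1] + Fa[j]) / p.B1;
  d.yt[0] = (Tt - p.Kse * s.yt[0]) / p.B2;
  d.yt[m + 1] = (Tt - p.Kse * s.yt[m + 1]) / p.B2;
  for (int j = 0; j < m; ++j)
    d.yt[j + 1] = (Tt - p.Klt * s.yt[j + 1] - Ft[j]) / p.B1;

  d.x = s.xd;
  d.xd = (Tag - Tant - p.Bp * s.xd - p.Kp * s.x) / p.Jp;
}

static inline void plant_axpy(PlantState &out, const PlantState &s,
                              const PlantState &d, double h, int m) {
  out.x = s.x + h * d.x;
  out.xd = s.xd + h * d.xd;
  for (int j = 0; j < m + 2; ++j) {
    out.ya[j] = s.ya[j] + h * d.ya[j];
    out.yt[j] = s.yt[j] + h * d.yt[j];
  }
}

// Forcing traces are sampled on the output grid (dt); stage values are
// linearly interpolated.  Fag_groups: (nsamp x ngroups); group_of: fiber ->
// column index into Fag_groups.  Antagonist fibers share one trace.
// [[Rcpp::export]]
List cpp_simulate_plant(NumericMatrix Fag_groups, IntegerVector group_of,
                        NumericVector Fant_trace, List params,
                        NumericVector y0_ag, NumericVector y0_ant,
                        double x0, double xd0, double dt) {
  PlantPar p;
  p.Kse = as<double>(params["K_se"]); p.B2 = as<double>(params["B_2"]);
  p.Klt = as<double>(params["K_lt"]); p.B1 = as<double>(params["B_1"]);
  p.Jp = as<double>(params["J_p"]); p.Bp = as<double>(params["B_p"]);
  p.Kp = as<double>(params["K_p"]); p.r = as<double>(params["r"]);
  p.m = as<int>(params["m"]); p.ncol = as<int>(params["n"]);
  int m = p.m;
  int nsamp = Fant_trace.size();
  int nsteps = nsamp - 1;

  PlantState s, d1, d2, d3, d4, tmp;
  s.ya.assign(y0_ag.begin(), y0_ag.end());
  s.yt.assign(y0_ant.begin(), y0_ant.end());
  s.x = x0; s.xd = xd0;
  for (PlantState *ps : {&d1, &d2, &d3, &d4, &tmp}) {
    ps->ya.resize(m + 2); ps->yt.resize(m + 2);
  }

  std::vector<double> Fa0(m), Fa1(m), Fah(m), Ft3(3);
  NumericVector th(nsamp), thd(nsamp), Tagv(nsamp), Tantv(nsamp);
  const double rad2deg = 180.0 / M_PI;

  double Tag, Tant;
  for (int k = 0; k < nsamp; ++k) {
    for (int j = 0; j < m; ++j) Fa0[j] = Fag_groups(k, group_of[j]);
    double Ft0 = Fant_trace[k];
    std::vector<double> Ftv0(m, Ft0);
    plant_deriv(s, Fa0, Ftv0, p, d1, Tag, Tant);
    th[k] = s.x / p.r * rad2deg;
    thd[k] = s.xd / p.r * rad2deg;
    Tagv[k] = Tag; Tantv[k] = Tant;
    if (k == nsteps) break;
    if (std::fabs(th[k]) > 90.0)
      stop("plant instability: |theta| > 90 deg at t index %d", k);

    int k1 = k + 1;
    for (int j = 0; j < m; ++j) {
      Fa1[j] = Fag_groups(k1, group_of[j]);
      Fah[j] = 0.5 * (Fa0[j] + Fa1[j]);
    }
    double Ft1 = Fant_trace[k1], Fth = 0.5 * (Ft0 + Ft1);
    std::vector<double> Ftvh(m, Fth), Ftv1(m, Ft1);

    plant_axpy(tmp, s, d1, 0.5 * dt, m);
    plant_deriv(tmp, Fah, Ftvh, p, d2, Tag, Tant);
    plant_axpy(tmp, s, d2, 0.5 * dt, m);
    plant_deriv(tmp, Fah, Ftvh, p, d3, Tag, Tant);
    plant_axpy(tmp, s, d3, dt, m);
    plant_deriv(tmp, Fa1, Ftv1, p, d4, Tag, Tant);

    s.x += dt / 6.0 * (d1.x + 2 * d2.x + 2 * d3.x + d4.x);
    s.xd += dt / 6.0 * (d1.xd + 2 * d2.xd + 2 * d3.xd + d4.xd);
    for (int j = 0; j < m + 2; ++j) {
      s.ya[j] += dt / 6.0 * (d1.ya[j] + 2 * d2.ya[j] + 2 * d3.ya[j] + d4.ya[j]);
      s.yt[j] += dt / 6.0 * (d1.yt[j] + 2 * d2.yt[j] + 2 * d3.yt[j] + d4.yt[j]);
    }
  }
  return List::create(_["theta"] = th, _["theta_dot"] = thd,
                      _["T_ag"] = Tagv, _["T_ant"] = Tantv,
                      _["y_ag"] = NumericVector(s.ya.begin(), s.ya.end()),
                      _["y_ant"] = NumericVector(s.yt.begin(), s.yt.end()));
}

// ---------------------------------------------------------------------
// First-order low-pass filter, exact per sample for zero-order-hold input:
// F[k+1] = N[k] + (F[k] - N[k]) exp(-dt / tau[k]).
// ---------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_filter_first_order(NumericVector N, NumericVector tau,
                                     double F0, double dt) {
  int n = N.size();
  NumericVector F(n);
  F[0] = F0;
  for (int k = 0; k < n - 1; ++k)
    F[k + 1] = N[k] + (F[k] - N[k]) * std::exp(-dt / tau[k]);
  return F;
}
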