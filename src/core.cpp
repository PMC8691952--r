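// Compartmental cable + Hodgkin-Huxley + synapse integrator with a
// tree-sparse implicit Euler scheme, plus the forward-sensitivity
// (variational) system for d v / d w of tracked synapses.
//
// Units: mV, ms, uS, uF, nA; conductance densities arrive pre-divided by
// c_m (1/ms); synaptic/axial couplings arrive scaled by 1e-3/(c_m * area).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double trap(double x, double y) {
  // x / (1 - exp(-x/y)) with removable singularity at x = 0
  double u = x / y;
  if (std::fabs(u) < 1e-6) return y * (1.0 + u / 2.0);
  return x / (1.0 - std::exp(-u));
}

struct Rates { double a, b; };

// Hodgkin-Huxley rate functions (ms^-1); vt is the threshold-adjustment
// voltage, taumax the slow-K (p gate) time-constant scale.
static Rates rate_m(double v, double vt) {
  Rates r;
  r.a = 0.32 * trap(v - vt - 13.0, 4.0);
  r.b = 0.28 * trap(-(v - vt - 40.0), 5.0);
  return r;
}
static Rates rate_h(double v, double vt) {
  Rates r;
  r.a = 0.128 * std::exp(-(v - vt - 17.0) / 18.0);
  r.b = 4.0 / (1.0 + std::exp(-(v - vt - 40.0) / 5.0));
  return r;
}
static Rates rate_n(double v, double vt) {
  Rates r;
  r.a = 0.032 * trap(v - vt - 15.0, 5.0);
  r.b = 0.5 * std::exp(-(v - vt - 10.0) / 40.0);
  return r;
}
static Rates rate_p(double v, double taumax) {
  double pinf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  double taup = taumax / (3.3 * std::exp((v + 35.0) / 20.0) +
                          std::exp(-(v + 35.0) / 20.0));
  Rates r;
  r.a = pinf / taup;
  r.b = (1.0 - pinf) / taup;
  return r;
}
static Rates rate_q(double v) {
  // HCN gate (somato-dendritic Ih)
  Rates r;
  r.a = 0.00643 * trap(v + 154.9, 11.9);
  r.b = 0.193 * std::exp(v / 33.1);
  return r;
}

static Rates rate_of(int ch, double v, double vt, double taumax) {
  switch (ch) {
    case 0: return rate_m(v, vt);
    case 1: return rate_h(v, vt);
    case 2: return rate_n(v, vt);
    case 3: return rate_p(v, taumax);
    default: return rate_q(v);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_gating_rates(NumericVector v, int channel, double vt,
                               double taumax) {
  NumericMatrix out(v.size(), 2);
  for (int i = 0; i < v.size(); ++i) {
    Rates r = rate_of(channel, v[i], vt, taumax);
    out(i, 0) = r.a;
    out(i, 1) = r.b;
  }
  return out;
}

static inline double sigmoid_n(double v, double C, double rho) {
  return 1.0 / (1.0 + C * std::exp(-rho * v));
}

struct Core {
  int N, nsyn;
  std::vector<int> parent;            // -1 for root
  std::vector<double> gup, glo;       // G[par][i], G[i][par] for i>=1
  std::vector<double> gna, gk, gkm, gih, gl;
  double ena, ek, el, ehcn, ee, ei;
  double vt, taumax, nmda_c, nmda_rho, gamma;
  bool nmda_on, has_q;
  std::vector<int> syn_comp;
  std::vector<int> syn_e;
  std::vector<double> syn_w, syn_h;
  double tau_ar, tau_ad, tau_nr, tau_nd, tau_gr, tau_gd;
  double norm_a, norm_n, norm_g;
  double inj_scale;                   // soma: 1e-3/(c_m * area_0)

  // state
  std::vector<double> v, m, h, n, p, q;
  std::vector<double> xr1, xd1, xr2, xd2;   // AMPA/GABA and NMDA pairs
  double t;

  // scratch
  std::vector<double> D, B, diag, rhs, fac, vnew;
  std::vector<char> gated;

  void init_dims() {
    v.assign(N, el); m.assign(N, 0); h.assign(N, 0); n.assign(N, 0);
    p.assign(N, 0); q.assign(N, 0);
    xr1.assign(nsyn, 0); xd1.assign(nsyn, 0);
    xr2.assign(nsyn, 0); xd2.assign(nsyn, 0);
    D.assign(N, 0); B.assign(N, 0); diag.assign(N, 0); rhs.assign(N, 0);
    fac.assign(N, 0); vnew.assign(N, 0);
    gated.assign(N, 0);
    for (int i = 0; i < N; ++i)
      gated[i] = (gna[i] > 0 || gk[i] > 0 || gkm[i] > 0 || gih[i] > 0);
    t = 0.0;
  }

  void rest_gates() {
    for (int i = 0; i < N; ++i) {
      Rates rm = rate_m(v[i], vt), rh = rate_h(v[i], vt),
            rn = rate_n(v[i], vt), rp = rate_p(v[i], taumax),
            rq = rate_q(v[i]);
      m[i] = rm.a / (rm.a + rm.b);
      h[i] = rh.a / (rh.a + rh.b);
      n[i] = rn.a / (rn.a + rn.b);
      p[i] = rp.a / (rp.a + rp.b);
      q[i] = rq.a / (rq.a + rq.b);
    }
  }
};

struct SensState {
  // per tracked synapse: dv and gating sensitivities over compartments
  std::vector<double> dv, dm, dh, dn, dp, dq;
};

static void solve_tree(Core &C, double dt) {
  // assemble M = diag(1/dt + D - G_ii) with off-diag -G; Hines eliminate.
  // G_ii = -(sum of row couplings); here fold row sums from gup/glo.
  for (int i = 0; i < C.N; ++i) {
    C.diag[i] = 1.0 / dt + C.D[i];
    C.rhs[i] = C.v[i] / dt + C.B[i];
  }
  for (int i = 1; i < C.N; ++i) {
    // row i has coupling glo[i]*(v_par - v_i): diag += glo, offdiag -= glo
    C.diag[i] += C.glo[i];
    C.diag[C.parent[i]] += C.gup[i];
  }
  for (int i = C.N - 1; i >= 1; --i) {
    int par = C.parent[i];
    double f = (-C.gup[i]) / C.diag[i];
    C.fac[i] = f;
    C.diag[par] -= f * (-C.glo[i]);
    C.rhs[par] -= f * C.rhs[i];
  }
  C.vnew[0] = C.rhs[0] / C.diag[0];
  for (int i = 1; i < C.N; ++i)
    C.vnew[i] = (C.rhs[i] + C.glo[i] * C.vnew[C.parent[i]]) / C.diag[i];
}

static void solve_tree_rhs(const Core &C, std::vector<double> &r,
                           std::vector<double> &out) {
  // reuse factorization stored in C.fac / C.diag
  for (int i = C.N - 1; i >= 1; --i) r[C.parent[i]] -= C.fac[i] * r[i];
  out[0] = r[0] / C.diag[0];
  for (int i = 1; i < C.N; ++i)
    out[i] = (r[i] + C.glo[i] * out[C.parent[i]]) / C.diag[i];
}

// numeric voltage-derivatives of the rate functions (for the gating chain
// rule); h chosen well below the voltage scale of the rate curves
static inline void rate_deriv(int ch, double v, double vt, double taumax,
                              double &da, double &db) {
  const double hh = 1e-4;
  Rates rp = rate_of(ch, v + hh, vt, taumax);
  Rates rm = rate_of(ch, v - hh, vt, taumax);
  da = (rp.a - rm.a) / (2 * hh);
  db = (rp.b - rm.b) / (2 * hh);
}

// [[Rcpp::export]]
List cpp_simulate(List geom, List spec, List layout, List trains,
                  double horizon, double dt, NumericVector i_soma,
                  int record_every, bool record_all, bool early_stop,
                  double checkpoint_every, Nullable<NumericVector> init_state,
                  double t0, IntegerVector tracked,
                  NumericVector sample_times) {
  Core C;
  C.N = as<int>(geom["n"]);
  IntegerVector par = geom["parent"];
  NumericVector gup = geom["gup"], glo = geom["glo"];
  C.parent.assign(par.begin(), par.end());
  C.gup.assign(gup.begin(), gup.end());
  C.glo.assign(glo.begin(), glo.end());

  NumericVector gna = spec["gna"], gk = spec["gk"], gkm = spec["gkm"],
                gih = spec["gih"], gl = spec["gl"];
  C.gna.assign(gna.begin(), gna.end());
  C.gk.assign(gk.begin(), gk.end());
  C.gkm.assign(gkm.begin(), gkm.end());
  C.gih.assign(gih.begin(), gih.end());
  C.gl.assign(gl.begin(), gl.end());
  C.ena = spec["ena"]; C.ek = spec["ek"]; C.el = spec["el"];
  C.ehcn = spec["ehcn"]; C.ee = spec["ee"]; C.ei = spec["ei"];
  C.vt = spec["vt"]; C.taumax = spec["taumax"];
  C.nmda_c = spec["nmda_c"]; C.nmda_rho = spec["nmda_rho"];
  C.nmda_on = spec["nmda_on"];
  C.gamma = spec["gamma"];
  C.tau_ar = spec["tau_ar"]; C.tau_ad = spec["tau_ad"];
  C.tau_nr = spec["tau_nr"]; C.tau_nd = spec["tau_nd"];
  C.tau_gr = spec["tau_gr"]; C.tau_gd = spec["tau_gd"];
  C.inj_scale = spec["inj_scale"];
  C.has_q = false;
  for (double g : C.gih) if (g > 0) C.has_q = true;

  IntegerVector scomp = layout["comp0"];
  IntegerVector se = layout["is_e"];
  NumericVector sw = layout["w"], sh = layout["hscale"];
  C.nsyn = scomp.size();
  C.syn_comp.assign(scomp.begin(), scomp.end());
  C.syn_e.assign(se.begin(), se.end());
  C.syn_w.assign(sw.begin(), sw.end());
  C.syn_h.assign(sh.begin(), sh.end());

  auto peak_norm = [](double tr, double td) {
    double tpk = tr * td / (td - tr) * std::log(td / tr);
    return std::exp(-tpk / td) - std::exp(-tpk / tr);
  };
  C.norm_a = peak_norm(C.tau_ar, C.tau_ad);
  C.norm_n = peak_norm(C.tau_nr, C.tau_nd);
  C.norm_g = peak_norm(C.tau_gr, C.tau_gd);

  C.init_dims();
  C.t = t0;

  // spike trains: concatenated times + per-synapse offsets (0-based)
  NumericVector sp_times = trains["times"];
  IntegerVector sp_off = trains["offsets"];  // length nsyn+1
  std::vector<int> sp_ptr(C.nsyn);
  for (int j = 0; j < C.nsyn; ++j) {
    sp_ptr[j] = sp_off[j];
    while (sp_ptr[j] < sp_off[j + 1] && sp_times[sp_ptr[j]] <= t0) sp_ptr[j]++;
  }

  if (init_state.isNotNull()) {
    NumericVector st(init_state);
    int k = 0;
    for (int i = 0; i < C.N; ++i) C.v[i] = st[k++];
    for (int i = 0; i < C.N; ++i) C.m[i] = st[k++];
    for (int i = 0; i < C.N; ++i) C.h[i] = st[k++];
    for (int i = 0; i < C.N; ++i) C.n[i] = st[k++];
    for (int i = 0; i < C.N; ++i) C.p[i] = st[k++];
    for (int i = 0; i < C.N; ++i) C.q[i] = st[k++];
    for (int j = 0; j < C.nsyn; ++j) C.xr1[j] = st[k++];
    for (int j = 0; j < C.nsyn; ++j) C.xd1[j] = st[k++];
    for (int j = 0; j < C.nsyn; ++j) C.xr2[j] = st[k++];
    for (int j = 0; j < C.nsyn; ++j) C.xd2[j] = st[k++];
  } else {
    C.rest_gates();
  }

  int nsteps = (int)std::round(horizon / dt);
  bool inj_vec = i_soma.size() > 1;
  double inj_const = i_soma.size() >= 1 ? i_soma[0] : 0.0;

  // sensitivity setup
  int ntr = tracked.size();
  std::vector<SensState> S(ntr);
  for (int k = 0; k < ntr; ++k) {
    S[k].dv.assign(C.N, 0); S[k].dm.assign(C.N, 0); S[k].dh.assign(C.N, 0);
    S[k].dn.assign(C.N, 0); S[k].dp.assign(C.N, 0); S[k].dq.assign(C.N, 0);
  }
  int nsamp = sample_times.size();
  NumericMatrix sens_vsoma(nsamp, ntr);
  std::vector<int> samp_step(nsamp);
  for (int s = 0; s < nsamp; ++s)
    samp_step[s] = (int)std::round((sample_times[s] - t0) / dt);

  // recording
  int nrec = nsteps / record_every + 1;
  NumericVector rec_t(nrec), rec_v(nrec);
  NumericMatrix rec_all;
  if (record_all) rec_all = NumericMatrix(nrec, C.N);
  int ri = 0;
  rec_t[0] = C.t; rec_v[0] = C.v[0];
  if (record_all) for (int i = 0; i < C.N; ++i) rec_all(0, i) = C.v[i];
  ri = 1;

  // rolling voltage buffer for v(t_spike) = v(crossing - 2 ms)
  int back_steps = (int)std::round(2.0 / dt);
  int buf_len = back_steps + 2;
  NumericMatrix vbuf(buf_len, C.N);
  for (int i = 0; i < C.N; ++i) vbuf(0, i) = C.v[i];

  std::vector<double> spike_t;
  std::vector<std::vector<double>> spike_vd;

  // checkpoints
  int ckpt_every = checkpoint_every > 0 ?
      (int)std::round(checkpoint_every / dt) : 0;
  int state_len = 6 * C.N + 4 * C.nsyn;
  std::vector<double> ckpt_store;
  std::vector<double> ckpt_times;
  auto push_state = [&](std::vector<double> &dst) {
    dst.insert(dst.end(), C.v.begin(), C.v.end());
    dst.insert(dst.end(), C.m.begin(), C.m.end());
    dst.insert(dst.end(), C.h.begin(), C.h.end());
    dst.insert(dst.end(), C.n.begin(), C.n.end());
    dst.insert(dst.end(), C.p.begin(), C.p.end());
    dst.insert(dst.end(), C.q.begin(), C.q.end());
    dst.insert(dst.end(), C.xr1.begin(), C.xr1.end());
    dst.insert(dst.end(), C.xd1.begin(), C.xd1.end());
    dst.insert(dst.end(), C.xr2.begin(), C.xr2.end());
    dst.insert(dst.end(), C.xd2.begin(), C.xd2.end());
  };
  if (ckpt_every > 0) { ckpt_times.push_back(C.t); push_state(ckpt_store); }

  double dec_ar = std::exp(-dt / C.tau_ar), dec_ad = std::exp(-dt / C.tau_ad);
  double dec_nr = std::exp(-dt / C.tau_nr), dec_nd = std::exp(-dt / C.tau_nd);
  double dec_gr = std::exp(-dt / C.tau_gr), dec_gd = std::exp(-dt / C.tau_gd);

  std::vector<double> v_old(C.N);
  std::vector<double> mA(C.N), mB(C.N);   // gating chain scratch per channel
  std::vector<double> nmda_dcond(C.N);    // sum_E w h gamma/(1+g) gN sigma'
  std::vector<double> sens_rhs(C.N), sens_out(C.N);
  // per-channel chain coefficients, stored per compartment
  std::vector<double> cm_x(C.N), cm_v(C.N), ch_x(C.N), ch_v(C.N),
      cn_x(C.N), cn_v(C.N), cp_x(C.N), cp_v(C.N), cq_x(C.N), cq_v(C.N);

  bool stopped = false;
  int step_done = 0;

  for (int step = 0; step < nsteps && !stopped; ++step) {
    double tnew = t0 + (step + 1) * dt;
    std::copy(C.v.begin(), C.v.end(), v_old.begin());

    // 1. gating update (staggered, implicit in x, stale v), keep chain coefs
    for (int i = 0; i < C.N; ++i) {
      if (!C.gated[i]) continue;
      double vi = v_old[i];
      struct { int ch; std::vector<double> *x, *cx, *cv; } upd[5] = {
        {0, &C.m, &cm_x, &cm_v}, {1, &C.h, &ch_x, &ch_v},
        {2, &C.n, &cn_x, &cn_v}, {3, &C.p, &cp_x, &cp_v},
        {4, &C.q, &cq_x, &cq_v}
      };
      int nch = C.has_q ? 5 : 4;
      for (int u = 0; u < nch; ++u) {
        Rates r = rate_of(upd[u].ch, vi, C.vt, C.taumax);
        double da, db;
        rate_deriv(upd[u].ch, vi, C.vt, C.taumax, da, db);
        double den = 1.0 + dt * (r.a + r.b);
        double x = (*upd[u].x)[i];
        double xnew = (x + dt * r.a) / den;
        (*upd[u].cx)[i] = 1.0 / den;
        (*upd[u].cv)[i] = (dt * da * den - (x + dt * r.a) * dt * (da + db)) /
                          (den * den);
        (*upd[u].x)[i] = xnew;
      }
    }

    // 2. synaptic kinetics: exact decay + spikes in (t, tnew]
    for (int j = 0; j < C.nsyn; ++j) {
      if (C.syn_e[j]) {
        C.xr1[j] *= dec_ar; C.xd1[j] *= dec_ad;
        C.xr2[j] *= dec_nr; C.xd2[j] *= dec_nd;
      } else {
        C.xr1[j] *= dec_gr; C.xd1[j] *= dec_gd;
      }
      while (sp_ptr[j] < sp_off[j + 1] && sp_times[sp_ptr[j]] <= tnew) {
        double ts = sp_times[sp_ptr[j]];
        double lag = tnew - ts;
        if (C.syn_e[j]) {
          C.xr1[j] += std::exp(-lag / C.tau_ar);
          C.xd1[j] += std::exp(-lag / C.tau_ad);
          C.xr2[j] += std::exp(-lag / C.tau_nr);
          C.xd2[j] += std::exp(-lag / C.tau_nd);
        } else {
          C.xr1[j] += std::exp(-lag / C.tau_gr);
          C.xd1[j] += std::exp(-lag / C.tau_gd);
        }
        sp_ptr[j]++;
      }
    }

    // 3. assemble D, B
    std::fill(nmda_dcond.begin(), nmda_dcond.end(), 0.0);
    for (int i = 0; i < C.N; ++i) {
      double gact = C.gna[i] * C.m[i] * C.m[i] * C.m[i] * C.h[i];
      double gkn = C.gk[i] * C.n[i] * C.n[i] * C.n[i] * C.n[i];
      double gkm = C.gkm[i] * C.p[i];
      double gq = C.gih[i] * C.q[i];
      C.D[i] = C.gl[i] + gact + gkn + gkm + gq;
      C.B[i] = C.gl[i] * C.el + gact * C.ena + gkn * C.ek + gkm * C.ek +
               gq * C.ehcn;
    }
    for (int j = 0; j < C.nsyn; ++j) {
      int c = C.syn_comp[j];
      if (C.syn_e[j]) {
        double gA = (C.xd1[j] - C.xr1[j]) / C.norm_a;
        double gN = (C.xd2[j] - C.xr2[j]) / C.norm_n;
        double sig = C.nmda_on ? sigmoid_n(v_old[c], C.nmda_c, C.nmda_rho) : 1.0;
        double ge = C.syn_w[j] * C.syn_h[j] *
                    (gA / (1.0 + C.gamma) + C.gamma / (1.0 + C.gamma) * gN * sig);
        C.D[c] += ge;
        C.B[c] += ge * C.ee;
        if (C.nmda_on) {
          double dsig = C.nmda_rho * sig * (1.0 - sig);
          nmda_dcond[c] += C.syn_w[j] * C.syn_h[j] *
                           C.gamma / (1.0 + C.gamma) * gN * dsig;
        }
      } else {
        double gG = (C.xd1[j] - C.xr1[j]) / C.norm_g;
        double gi = C.syn_w[j] * C.syn_h[j] * gG;
        C.D[c] += gi;
        C.B[c] += gi * C.ei;
      }
    }
    double inj = inj_vec ? i_soma[step] : inj_const;
    C.B[0] += inj * C.inj_scale;

    // 4. voltage solve
    solve_tree(C, dt);

    // 5. variational update (exact derivative of the discrete map)
    for (int k = 0; k < ntr; ++k) {
      SensState &s = S[k];
      int jt = tracked[k];
      // gating sensitivities via chain coefficients (use stale dv)
      for (int i = 0; i < C.N; ++i) {
        if (!C.gated[i]) continue;
        double dvo = s.dv[i];
        s.dm[i] = cm_x[i] * s.dm[i] + cm_v[i] * dvo;
        s.dh[i] = ch_x[i] * s.dh[i] + ch_v[i] * dvo;
        s.dn[i] = cn_x[i] * s.dn[i] + cn_v[i] * dvo;
        s.dp[i] = cp_x[i] * s.dp[i] + cp_v[i] * dvo;
        if (C.has_q) s.dq[i] = cq_x[i] * s.dq[i] + cq_v[i] * dvo;
      }
      for (int i = 0; i < C.N; ++i) {
        double F = s.dv[i] / dt;
        // NMDA conductance depends on stale v
        if (nmda_dcond[i] != 0.0)
          F -= nmda_dcond[i] * s.dv[i] * (C.vnew[i] - C.ee);
        if (C.gated[i]) {
          double m2 = C.m[i] * C.m[i];
          F -= C.gna[i] * (3.0 * m2 * C.h[i] * s.dm[i] +
                           m2 * C.m[i] * s.dh[i]) * (C.vnew[i] - C.ena);
          F -= C.gk[i] * 4.0 * C.n[i] * C.n[i] * C.n[i] * s.dn[i] *
               (C.vnew[i] - C.ek);
          F -= C.gkm[i] * s.dp[i] * (C.vnew[i] - C.ek);
          if (C.has_q)
            F -= C.gih[i] * s.dq[i] * (C.vnew[i] - C.ehcn);
        }
        sens_rhs[i] = F;
      }
      // direct synaptic drive of the tracked weight
      {
        int c = C.syn_comp[jt];
        if (C.syn_e[jt]) {
          double gA = (C.xd1[jt] - C.xr1[jt]) / C.norm_a;
          double gN = (C.xd2[jt] - C.xr2[jt]) / C.norm_n;
          double sig = C.nmda_on ? sigmoid_n(v_old[c], C.nmda_c, C.nmda_rho)
                                 : 1.0;
          double gmix = C.syn_h[jt] * (gA / (1.0 + C.gamma) +
                        C.gamma / (1.0 + C.gamma) * gN * sig);
          sens_rhs[c] -= gmix * (C.vnew[c] - C.ee);
        } else {
          double gG = (C.xd1[jt] - C.xr1[jt]) / C.norm_g;
          sens_rhs[c] -= C.syn_h[jt] * gG * (C.vnew[c] - C.ei);
        }
      }
      solve_tree_rhs(C, sens_rhs, sens_out);
      std::copy(sens_out.begin(), sens_out.end(), s.dv.begin());
    }

    double v0_old = C.v[0];
    std::copy(C.vnew.begin(), C.vnew.end(), C.v.begin());
    C.t = tnew;
    step_done = step + 1;

    if (!std::isfinite(C.v[0]))
      stop("numerical instability (non-finite voltage) at t = %f ms", C.t);

    // ring buffer of voltages
    int bi = (step + 1) % buf_len;
    for (int i = 0; i < C.N; ++i) vbuf(bi, i) = C.v[i];

    // sensitivity sampling
    for (int sIdx = 0; sIdx < nsamp; ++sIdx) {
      if (samp_step[sIdx] == step + 1) {
        for (int k = 0; k < ntr; ++k) sens_vsoma(sIdx, k) = S[k].dv[0];
      }
    }

    // spike detection: upward 0 mV crossing; t_spike = crossing - 2 ms
    if (v0_old < 0.0 && C.v[0] >= 0.0) {
      double frac = (0.0 - v0_old) / (C.v[0] - v0_old);
      double t_cross = C.t - dt + frac * dt;
      double t_sp = t_cross - 2.0;
      spike_t.push_back(t_sp);
      // voltage snapshot back_steps ago (approximately t_spike)
      int target = (step + 1) - back_steps;
      std::vector<double> vd(C.N);
      if (target >= 0) {
        int tb = target % buf_len;
        for (int i = 0; i < C.N; ++i) vd[i] = vbuf(tb, i);
      } else {
        for (int i = 0; i < C.N; ++i) vd[i] = vbuf(0, i);
      }
      spike_vd.push_back(vd);
      if (early_stop) stopped = true;
    }

    if ((step + 1) % record_every == 0 && ri < nrec) {
      rec_t[ri] = C.t;
      rec_v[ri] = C.v[0];
      if (record_all) for (int i = 0; i < C.N; ++i) rec_all(ri, i) = C.v[i];
      ri++;
    }
    if (ckpt_every > 0 && (step + 1) % ckpt_every == 0) {
      ckpt_times.push_back(C.t);
      push_state(ckpt_store);
    }
  }

  // outputs
  NumericVector out_t(ri), out_v(ri);
  for (int i = 0; i < ri; ++i) { out_t[i] = rec_t[i]; out_v[i] = rec_v[i]; }
  NumericMatrix out_all;
  if (record_all) {
    out_all = NumericMatrix(ri, C.N);
    for (int r = 0; r < ri; ++r)
      for (int i = 0; i < C.N; ++i) out_all(r, i) = rec_all(r, i);
  }
  int nspk = spike_t.size();
  NumericVector spikes(nspk);
  NumericMatrix spike_vdend(nspk, C.N);
  for (int s = 0; s < nspk; ++s) {
    spikes[s] = spike_t[s];
    for (int i = 0; i < C.N; ++i) spike_vdend(s, i) = spike_vd[s][i];
  }
  std::vector<double> fin;
  fin.reserve(state_len);
  push_state(fin);

  List out = List::create(
    _["times"] = out_t, _["v_soma"] = out_v,
    _["spikes"] = spikes, _["spike_vdend"] = spike_vdend,
    _["final_state"] = NumericVector(fin.begin(), fin.end()),
    _["t_end"] = C.t, _["steps"] = step_done);
  if (record_all) out["v_all"] = out_all;
  if (ckpt_every > 0) {
    int nck = ckpt_times.size();
    NumericMatrix ck(nck, state_len);
    for (int r = 0; r < nck; ++r)
      for (int cidx = 0; cidx < state_len; ++cidx)
        ck(r, cidx) = ckpt_store[(size_t)r * state_len + cidx];
    out["checkpoint_times"] = NumericVector(ckpt_times.begin(), ckpt_times.end());
    out["checkpoints"] = ck;
  }
  if (ntr > 0) {
    out["sens_vsoma"] = sens_vsoma;
    NumericMatrix dv_final(ntr, C.N);
    for (int k = 0; k < ntr; ++k)
      for (int i = 0; i < C.N; ++i) dv_final(k, i) = S[k].dv[i];
    out["sens_dv_final"] = dv_final;
  }
  return out;
}
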