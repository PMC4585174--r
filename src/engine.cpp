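// Hybrid deterministic/stochastic driver. One iteration: (1) solve every
// dyadic cleft quasistatically for self-consistent channel currents,
// (2) advance the bulk PDE and membrane ODE over the deterministic step
// tau_det with fluxes frozen at the step start, (3) predict channel
// transitions over the window from integrated-propensity clocks using
// start and predicted end values, (4) select the stochastic step tau_stoc
// from the event-batching rule, (5) re-advance the deterministic states
// to tau_stoc, (6) re-integrate the clocks against the accepted update
// (so no event triggered by the update is missed) and realize the due
// conductance changes at the end of the step.
#include "cicr.h"
#include <chrono>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Cru {
  int n;
  arma::mat eta;
  std::vector<double> Z, gch;
  std::vector<int> isryr;
  std::vector<int> st;
  std::vector<double> acc, th;
  std::vector<int> src_cells, rim_cells;
  int center_cell;
  double vjsr, cjsr;
  std::vector<double> cur, cdi0, cdi1;
  double sum_ryr = 0, sum_lcc = 0;
  double cjsr_pred = 0, refill_mean = 0;
  double cbulk0 = 0, cbulk1 = 0, Sloc = 0;
};

struct EngineCfg {
  double rtol, atol, lin_tol, tau_max, tau_min, tau0;
  double cap_frac; bool force_ns1;
  double jsr_substep, tau_refill, ncsq, Bcsq, Kcsq;
  bool no_lcc, event_log;
  double kd_fluo, fmax_fluo;
  double ical_scale, inaca_scale, vcell, acell, omega;
  double vcyt_frac, vsr_frac, delta, c_ext, g_ryr, mem_hmax;
  int stim_mode;  // 0 current injection, 1 voltage offset
};

static double interp_wave(const std::vector<double>& t,
                          const std::vector<double>& v, double x) {
  if (x <= t.front()) return v.front();
  if (x >= t.back()) return v.back();
  size_t hi = std::upper_bound(t.begin(), t.end(), x) - t.begin();
  size_t lo = hi - 1;
  double w = (x - t[lo]) / (t[hi] - t[lo]);
  return v[lo] + w * (v[hi] - v[lo]);
}

// quasistatic cleft solve at (cbulk, cjsr, V); fills cur and cdi
static void cleft_solve(Cru& C, double cbulk, double cjsr, double V,
                        const EngineCfg& cfg, std::vector<double>& cdi,
                        bool update_currents) {
  int n = C.n;
  std::vector<int> oo;
  for (int i = 0; i < n; ++i) {
    bool open = C.isryr[i] ? (C.st[i] == 1)
                           : (!cfg.no_lcc && lcc_is_open(C.st[i]));
    if (open) oo.push_back(i);
  }
  if (update_currents) std::fill(C.cur.begin(), C.cur.end(), 0.0);
  if (!oo.empty()) {
    int m = oo.size();
    arma::mat M(m, m);
    arma::vec rhs(m), Avec(m), Bvec(m);
    double dV = cfg.delta * V;
    double edv = std::exp(-dV);
    for (int k = 0; k < m; ++k) {
      int ch = oo[k];
      if (C.isryr[ch]) {
        Avec(k) = C.gch[ch] * cjsr; Bvec(k) = C.gch[ch];
      } else if (std::fabs(dV) < 1e-9) {
        Avec(k) = C.gch[ch] * cfg.c_ext; Bvec(k) = C.gch[ch];
      } else {
        double f = C.gch[ch] * dV / (1.0 - edv);
        Avec(k) = f * cfg.c_ext * edv; Bvec(k) = f;
      }
    }
    for (int k = 0; k < m; ++k) {
      for (int l = 0; l < m; ++l)
        M(k, l) = (k == l ? 1.0 : 0.0) + Bvec(k) * C.eta(oo[k], oo[l]);
      rhs(k) = Avec(k) - Bvec(k) * C.Z[oo[k]] * cbulk;
    }
    arma::vec I;
    if (!arma::solve(I, M, rhs)) stop("singular cleft system");
    std::vector<double> Ifull(n, 0.0);
    for (int k = 0; k < m; ++k) Ifull[oo[k]] = I(k);
    for (int i = 0; i < n; ++i) {
      double s = C.Z[i] * cbulk;
      for (int k = 0; k < m; ++k) s += C.eta(i, oo[k]) * I(k);
      cdi[i] = std::max(s, 0.0);
    }
    if (update_currents) {
      C.sum_ryr = 0; C.sum_lcc = 0;
      for (int k = 0; k < m; ++k) {
        int ch = oo[k];
        C.cur[ch] = I(k);
        if (C.isryr[ch]) C.sum_ryr += I(k); else C.sum_lcc += I(k);
      }
    }
  } else {
    for (int i = 0; i < n; ++i) cdi[i] = C.Z[i] * cbulk;
    if (update_currents) { C.sum_ryr = 0; C.sum_lcc = 0; }
  }
}

static void jsr_integrate(Cru& C, double tau, const EngineCfg& cfg) {
  int nsub = std::max(1, (int)std::ceil(tau / cfg.jsr_substep));
  double hh = tau / nsub;
  double c = C.cjsr, refint = 0.0;
  double drain = C.vjsr > 0 ? C.sum_ryr / C.vjsr : 0.0;
  for (int s = 0; s < nsub; ++s) {
    double d = cfg.Kcsq + c;
    double b = 1.0 / (1.0 + cfg.ncsq * cfg.Kcsq * cfg.Bcsq / (d * d));
    double num = c + hh * b * (C.Sloc / cfg.tau_refill - drain);
    double cn = num / (1.0 + hh * b / cfg.tau_refill);
    if (cn < 0) cn = 0;
    refint += hh * (C.Sloc - 0.5 * (c + cn)) / cfg.tau_refill;
    c = cn;
  }
  C.cjsr_pred = c;
  C.refill_mean = refint / tau;
}

// Integrate the gating clocks of one CRU over [0, tau] with linear
// interpolation of the local conditions between the step endpoints.
// Returns the first conductance-changing crossing time (INFINITY if
// none). In commit mode, neutral transitions are executed, conductance
// flips are applied (at step end), and clocks are updated in place.
static double gate_cru(Cru& C, double tau, double V0, double V1,
                       double cjsr0, double cjsr1, const RyrPars& RP,
                       const LccPars& LP, std::mt19937_64& rng,
                       bool commit, double& max_kopen,
                       std::vector<int>* ev_ch, std::vector<int>* ev_from,
                       std::vector<int>* ev_to) {
  std::exponential_distribution<double> rexp(1.0);
  std::uniform_real_distribution<double> runif(0.0, 1.0);
  double first = INFINITY;
  double ra[8], rb[8], rc[8];
  int da[8], db[8];
  for (int ch = 0; ch < C.n; ++ch) {
    int s = C.st[ch];
    double A = C.acc[ch], th = C.th[ch];
    double tcur = 0.0;
    bool ryr = C.isryr[ch] != 0;
    int flips = -1;
    for (int guard = 0; guard < 100000; ++guard) {
      double w0 = 1.0 - tcur / tau, w1 = tcur / tau;
      double cdi_a = C.cdi0[ch] * w0 + C.cdi1[ch] * w1;
      double cjsr_a = cjsr0 * w0 + cjsr1 * w1;
      int nr;
      if (ryr) {
        nr = ryr_exits(s, cdi_a, cjsr_a, RP, ra, da);
        ryr_exits(s, C.cdi1[ch], cjsr1, RP, rb, db);
      } else {
        double Va = V0 * w0 + V1 * w1;
        LccCtx ca, cb;
        lcc_ctx(Va, LP, ca);
        lcc_ctx(V1, LP, cb);
        // Ca-inactivation senses the surface-enhanced mouth value; the
        // printed thresholds are rescaled for that amplitude
        nr = lcc_exits(s, cdi_a, LP, ca, ra, da);
        lcc_exits(s, C.cdi1[ch], LP, cb, rb, db);
      }
      if (RP.scheme == 2 && ryr && s == 0) {
        if (ra[0] > max_kopen) max_kopen = ra[0];
        if (rb[0] > max_kopen) max_kopen = rb[0];
      }
      double la = 0, lb = 0;
      for (int k = 0; k < nr; ++k) { la += ra[k]; lb += rb[k]; }
      double span = tau - tcur;
      double L = 0.5 * (la + lb) * span;
      if (A + L < th || L <= 0.0) { A += L; break; }
      // crossing: A + la s + (lb-la)/span * s^2/2 = th
      double need = th - A;
      double slope = (lb - la) / span;
      double sstar;
      if (std::fabs(slope) < 1e-14) {
        sstar = la > 0 ? need / la : span;
      } else {
        double disc = la * la + 2.0 * slope * need;
        sstar = disc > 0 ? (-la + std::sqrt(disc)) / slope : span;
      }
      sstar = std::min(std::max(sstar, 0.0), span);
      double tc = tcur + sstar;
      double wc = sstar / span;
      double lc = 0.0;
      for (int k = 0; k < nr; ++k) {
        rc[k] = ra[k] + (rb[k] - ra[k]) * wc;
        lc += rc[k];
      }
      int dest = da[nr - 1];
      if (lc > 0) {
        double u = runif(rng) * lc, csum = 0.0;
        for (int k = 0; k < nr; ++k) {
          csum += rc[k];
          if (u <= csum) { dest = da[k]; break; }
        }
      }
      bool open_now = ryr ? (s == 1) : lcc_is_open(s);
      bool open_new = ryr ? (dest == 1) : lcc_is_open(dest);
      if (open_now != open_new) {
        if (tc < first) first = tc;
        if (commit) {
          flips = dest;
          A = 0.0; th = rexp(rng);
        }
        break;
      }
      s = dest; tcur = tc;
      A = 0.0; th = rexp(rng);
    }
    if (commit) {
      if (flips >= 0) {
        if (ev_ch) {
          ev_ch->push_back(ch); ev_from->push_back(s);
          ev_to->push_back(flips);
        }
        C.st[ch] = flips;
      } else {
        C.st[ch] = s;
      }
      C.acc[ch] = A; C.th[ch] = th;
    }
  }
  return first;
}

// [[Rcpp::export]]
List run_engine_cpp(NumericVector y0, IntegerVector dims, double h,
                    List pde_pars, List crus_in, List ryr_in, List lcc_in,
                    List mem_in, List protocol, List numerics) {
  Grid g{dims[0], dims[1], dims[2], dims[0] * dims[1] * dims[2], h};
  if ((int)y0.size() != 6 * g.N) stop("state length mismatch");
  const int N = g.N;

  EngineCfg cfg;
  cfg.rtol = numerics["rtol"]; cfg.atol = numerics["atol"];
  cfg.lin_tol = numerics["lin_tol"];
  cfg.tau_max = numerics["tau_max"]; cfg.tau_min = numerics["tau_min"];
  cfg.tau0 = numerics["tau0"];
  cfg.cap_frac = numerics["cap_frac"];
  cfg.force_ns1 = as<bool>(numerics["force_ns1"]);
  cfg.jsr_substep = numerics["jsr_substep"];
  cfg.tau_refill = numerics["tau_refill"];
  cfg.ncsq = numerics["n_csqn"]; cfg.Bcsq = numerics["B_csqn"];
  cfg.Kcsq = numerics["K_csqn"];
  cfg.no_lcc = as<bool>(numerics["no_lcc"]);
  cfg.event_log = as<bool>(numerics["event_log"]);
  cfg.kd_fluo = numerics["kd_fluo"]; cfg.fmax_fluo = numerics["fmax_fluo"];
  cfg.ical_scale = numerics["ical_scale"];
  cfg.inaca_scale = numerics["inaca_scale"];
  cfg.vcell = numerics["vcell"]; cfg.acell = numerics["acell"];
  cfg.omega = numerics["omega"];
  cfg.vcyt_frac = numerics["vcyt_frac"]; cfg.vsr_frac = numerics["vsr_frac"];
  cfg.delta = numerics["delta"]; cfg.c_ext = numerics["c_ext"];
  cfg.mem_hmax = numerics["mem_hmax"];
  cfg.stim_mode = as<int>(numerics["stim_mode"]);
  unsigned long seed = (unsigned long)as<double>(numerics["seed"]);

  RyrPars RP;
  RP.scheme = as<int>(ryr_in["scheme"]);
  RP.g = ryr_in["g"];
  RP.kacmax = ryr_in["kacmax"]; RP.kinmax = ryr_in["kinmax"];
  RP.Kac = ryr_in["Kac"]; RP.Kin = ryr_in["Kin"];
  RP.kom = ryr_in["kom"]; RP.kim = ryr_in["kim"];
  RP.Kjsr = ryr_in["Kjsr"]; RP.lambda = ryr_in["lambda"];
  RP.Aopen = ryr_in["Aopen"]; RP.popen = ryr_in["popen"];
  RP.kopenmax = ryr_in["kopenmax"]; RP.Aclose = ryr_in["Aclose"];
  RP.pclose = ryr_in["pclose"]; RP.kclosemax = ryr_in["kclosemax"];
  RP.kplus = ryr_in["kplus"]; RP.eta = ryr_in["eta"];
  RP.kclose = ryr_in["kclose"]; RP.phib = ryr_in["phib"];
  RP.phik = ryr_in["phik"];

  LccPars LP;
  LP.JL = lcc_in["JL"]; LP.kp0 = lcc_in["kp0"]; LP.cpbar = lcc_in["cpbar"];
  LP.taupo = lcc_in["taupo"]; LP.r1 = lcc_in["r1"]; LP.r2 = lcc_in["r2"];
  LP.s1p = lcc_in["s1p"]; LP.k1p = lcc_in["k1p"]; LP.k2 = lcc_in["k2"];
  LP.k21p = lcc_in["k21p"]; LP.Tba = lcc_in["Tba"];

  // CRUs
  int nc = crus_in.size();
  std::vector<Cru> crus(nc);
  for (int q = 0; q < nc; ++q) {
    List ci = crus_in[q];
    Cru& C = crus[q];
    NumericMatrix eta = ci["eta"];
    C.n = eta.nrow();
    C.eta = arma::mat(eta.begin(), C.n, C.n);
    NumericVector Z = ci["Z"], gch = ci["g"];
    IntegerVector isr = ci["is_ryr"], st0 = ci["states0"];
    C.Z.assign(Z.begin(), Z.end());
    C.gch.assign(gch.begin(), gch.end());
    C.isryr.assign(isr.begin(), isr.end());
    C.st.assign(st0.begin(), st0.end());
    C.acc.assign(C.n, 0.0);
    C.th.assign(C.n, 0.0);
    IntegerVector sc = ci["src_cells"], rc = ci["rim_cells"];
    C.src_cells.assign(sc.begin(), sc.end());
    C.rim_cells.assign(rc.begin(), rc.end());
    C.center_cell = as<int>(ci["center_cell"]);
    C.vjsr = ci["v_jsr"];
    C.cjsr = ci["cjsr0"];
    C.cur.assign(C.n, 0.0);
    C.cdi0.assign(C.n, 0.0);
    C.cdi1.assign(C.n, 0.0);
  }

  // membrane
  List mem_pars = mem_in["pars"];
  MemPars MP = unpack_mem(mem_pars);
  NumericVector memy0 = mem_in["y0"];
  double memy[MEM_NY], memy_pred[MEM_NY];
  for (int i = 0; i < MEM_NY; ++i) memy[i] = memy0[i];
  bool clamp = as<bool>(mem_in["clamp"]);
  std::vector<double> wave_t, wave_v;
  if (clamp) {
    NumericVector wt = mem_in["wave_t"], wv = mem_in["wave_v"];
    wave_t.assign(wt.begin(), wt.end());
    wave_v.assign(wv.begin(), wv.end());
  }

  // protocol
  NumericVector stim_times = protocol["stim_times"];
  double stim_amp = protocol["stim_amp"];
  double stim_dur = protocol["stim_dur"];
  double t_end = protocol["t_end"];
  double dt_out = protocol["dt_out"];
  NumericVector snap_times = protocol["snap_times"];

  PdeSolver pde;
  pde.init(g, unpack_pde(pde_pars, N));
  pde.lin_tol = cfg.lin_tol;
  pde.err_skip.assign(N, 0);
  for (auto& C : crus)
    for (int idx : C.src_cells) {
      pde.err_skip[idx] = 1;
      // face neighbors share the sub-grid source halo
      int ix = idx % g.nx, iy = (idx / g.nx) % g.ny, iz = idx / (g.nx * g.ny);
      if (ix > 0) pde.err_skip[idx - 1] = 1;
      if (ix < g.nx - 1) pde.err_skip[idx + 1] = 1;
      if (iy > 0) pde.err_skip[idx - g.nx] = 1;
      if (iy < g.ny - 1) pde.err_skip[idx + g.nx] = 1;
      if (iz > 0) pde.err_skip[idx - g.nx * g.ny] = 1;
      if (iz < g.nz - 1) pde.err_skip[idx + g.nx * g.ny] = 1;
    }

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> ycand(6 * N), ycand2(6 * N);
  std::vector<double> jcru(N, 0.0), jjsr(N, 0.0);
  pde.jcru = jcru.data();
  pde.jjsr = jjsr.data();

  std::mt19937_64 rng(seed ? seed : 1u);
  std::exponential_distribution<double> rexp(1.0);
  for (auto& C : crus)
    for (int i = 0; i < C.n; ++i) C.th[i] = rexp(rng);

  // output
  int n_out = (int)std::floor(t_end / dt_out + 1e-9) + 1;
  const int NCOL = 31;
  NumericMatrix traces(n_out, NCOL);
  CharacterVector cn = CharacterVector::create(
    "t", "V", "i_cal", "i_naca", "i_na", "i_k1", "i_kr", "i_ks", "i_tof",
    "i_tos", "i_nak", "c_avg", "c_exp", "S_avg", "Bsr_avg", "b_tnc_avg",
    "b_cam_avg", "b_fluo_avg", "cjsr_avg", "j_rel", "j_ca", "j_up",
    "j_naca", "frac_ryr_open", "frac_lcc_open", "jrel_cum", "jca_cum",
    "total_ca", "max_kopen", "tau_det", "n_events");
  colnames(traces) = cn;
  int out_idx = 0;
  int n_snap = snap_times.size();
  NumericMatrix snap_c(n_snap > 0 ? N : 1, std::max(n_snap, 1));
  NumericMatrix snap_S(n_snap > 0 ? N : 1, std::max(n_snap, 1));
  int snap_idx = 0;
  std::vector<double> ev_t; std::vector<int> ev_cru, ev_ch, ev_from, ev_to;

  double t = 0.0, tau_prop = cfg.tau0;
  using clk = std::chrono::steady_clock;
  double tm_cleft = 0, tm_pde = 0, tm_gate = 0, tm_jsr = 0, tm_mem = 0,
    tm_obs = 0;
  auto tic = clk::now();
  auto lap_tm = [&tic]() {
    auto now = clk::now();
    double d = std::chrono::duration<double>(now - tic).count();
    tic = now;
    return d;
  };
  double jrel_cum = 0.0, jca_cum = 0.0, max_kopen = 0.0;
  long n_steps = 0, n_rejects = 0;
  double last_tau_det = cfg.tau0;
  int last_nev = 0;
  int n_ryr_tot = 0, n_lcc_tot = 0;
  for (auto& C : crus)
    for (int i = 0; i < C.n; ++i) (C.isryr[i] ? n_ryr_tot : n_lcc_tot)++;

  double next_stim_offset = -1.0;   // pending voltage-offset stim time
  size_t stim_applied = 0;

  while (true) {
    Rcpp::checkUserInterrupt();
    // --- gather CRU inputs and solve clefts at time t
    lap_tm();
    const double* c = y.data();
    const double* S = y.data() + 4 * N;
    double V0 = clamp ? interp_wave(wave_t, wave_v, t) : memy[0];
    double sum_ryr_all = 0.0, sum_lcc_all = 0.0;
    int open_ryr = 0, open_lcc = 0;
    for (auto& C : crus) {
      double cb = 0.0;
      for (int idx : C.rim_cells) cb += c[idx];
      C.cbulk0 = cb / C.rim_cells.size();
      C.Sloc = S[C.center_cell];
      cleft_solve(C, C.cbulk0, C.cjsr, V0, cfg, C.cdi0, true);
      sum_ryr_all += C.sum_ryr;
      sum_lcc_all += C.sum_lcc;
      for (int i = 0; i < C.n; ++i) {
        if (C.isryr[i]) { if (C.st[i] == 1) ++open_ryr; }
        else if (C.st[i] == 2) ++open_lcc;
      }
    }
    tm_cleft += lap_tm();
    double ical = -cfg.ical_scale * sum_lcc_all;
    // NCX integrals (Eq 12) from the current field
    double ea = std::exp(pde.P.xi * V0 * pde.P.frt);
    double eb = std::exp((pde.P.xi - 1.0) * V0 * pde.P.frt);
    double jn_bulk = 0.0, jn_pm = 0.0;
    long n_faces = 0;
    if (pde.P.ncx_on) {
      for (int i = 0; i < N; ++i) {
        double base = ncx_base(c[i], pde.P, ea, eb);
        jn_bulk += pde.P.f_cell[i] * base;
        if (pde.P.pm_on && pde.P.memb[i] > 0) {
          jn_pm += pde.P.memb[i] * pde.P.f_surf * base * pde.P.depth;
          n_faces += pde.P.memb[i];
        }
      }
    }
    double mean_jb = jn_bulk / N;
    double mean_jpm = n_faces > 0 ? jn_pm / n_faces : 0.0;
    double inaca = cfg.inaca_scale *
      (cfg.vcell * mean_jb + cfg.acell * mean_jpm);

    double c_avg = 0, S_avg = 0, bt_avg = 0, bc_avg = 0, bf_avg = 0,
      bs_avg = 0;
    for (int i = 0; i < N; ++i) {
      c_avg += y[i]; bt_avg += y[N + i]; bc_avg += y[2 * N + i];
      bf_avg += y[3 * N + i]; S_avg += y[4 * N + i]; bs_avg += y[5 * N + i];
    }
    c_avg /= N; bt_avg /= N; bc_avg /= N; bf_avg /= N; S_avg /= N;
    bs_avg /= N;

    // --- record on the output clock
    while (out_idx < n_out && t >= out_idx * dt_out - 1e-9) {
      double dy[MEM_NY]; MemCurrents mc{0, 0, 0, 0, 0, 0, 0};
      if (!clamp) mem_derivs(memy, MP, ical, inaca, 0.0, c_avg, dy, &mc);
      double cexp = bf_avg < cfg.fmax_fluo
        ? cfg.kd_fluo * bf_avg / (cfg.fmax_fluo - bf_avg) : R_PosInf;
      double cjsr_m = 0.0, jsr_amt = 0.0;
      for (auto& C : crus) {
        cjsr_m += C.cjsr;
        jsr_amt += C.vjsr * (C.cjsr + cfg.ncsq * cfg.Bcsq * C.cjsr /
                             (cfg.Kcsq + C.cjsr));
      }
      cjsr_m /= std::max(nc, 1);
      double total_ca = cfg.vcyt_frac * (c_avg + bt_avg + bc_avg + bf_avg) +
        cfg.vsr_frac * (S_avg + bs_avg) + jsr_amt / cfg.omega;
      double j_up = 0.0;
      if (pde.P.pump_on) {
        for (int i = 0; i < N; ++i) {
          double cc2 = y[i] * y[i];
          j_up += pde.P.pump_vmax * cc2 /
            (pde.P.pump_kp * pde.P.pump_kp + cc2);
        }
        j_up /= N;
      }
      double* row = &traces(out_idx, 0);
      double vals[NCOL] = {
        t, V0, ical, inaca, mc.ina, mc.ik1, mc.ikr, mc.iks, mc.itof,
        mc.itos, mc.inak, c_avg, cexp, S_avg, bs_avg, bt_avg, bc_avg,
        bf_avg, cjsr_m,
        sum_ryr_all / (cfg.omega * cfg.vcyt_frac),
        sum_lcc_all / (cfg.omega * cfg.vcyt_frac),
        j_up, mean_jb,
        n_ryr_tot ? (double)open_ryr / n_ryr_tot : 0.0,
        n_lcc_tot ? (double)open_lcc / n_lcc_tot : 0.0,
        jrel_cum, jca_cum, total_ca, max_kopen, last_tau_det,
        (double)last_nev};
      for (int k = 0; k < NCOL; ++k) row[k * n_out] = vals[k];
      ++out_idx;
    }
    while (snap_idx < n_snap && t >= snap_times[snap_idx] - 1e-9) {
      for (int i = 0; i < N; ++i) {
        snap_c(i, snap_idx) = y[i];
        snap_S(i, snap_idx) = y[4 * N + i];
      }
      ++snap_idx;
    }
    tm_obs += lap_tm();
    if (t >= t_end - 1e-9) break;

    // --- stimulus bookkeeping
    double istim = 0.0;
    for (int k = 0; k < stim_times.size(); ++k) {
      if (t >= stim_times[k] - 1e-9 && t < stim_times[k] + stim_dur - 1e-9)
        istim = -stim_amp;
    }
    if (cfg.stim_mode == 1) {
      istim = 0.0;
      if (stim_applied < (size_t)stim_times.size() &&
          t >= stim_times[stim_applied] - 1e-9) {
        memy[0] += stim_amp;   // direct voltage offset
        ++stim_applied;
      }
    }

    // --- propose deterministic step, capped at protocol boundaries
    double tau = std::min(tau_prop, cfg.tau_max);
    double cap = t_end - t;
    cap = std::min(cap, out_idx * dt_out - t);
    for (int k = 0; k < stim_times.size(); ++k) {
      double a = stim_times[k] - t, b = stim_times[k] + stim_dur - t;
      if (a > 1e-9) cap = std::min(cap, a);
      if (b > 1e-9) cap = std::min(cap, b);
    }
    if (snap_idx < n_snap) {
      double a = snap_times[snap_idx] - t;
      if (a > 1e-9) cap = std::min(cap, a);
    }
    tau = std::max(std::min(tau, cap), cfg.tau_min);

    // --- deterministic trial over tau (jSR + sources + PDE)
    StepResult res;
    lap_tm();
    for (;;) {
      for (auto& C : crus) jsr_integrate(C, tau, cfg);
      tm_jsr += lap_tm();
      std::fill(jcru.begin(), jcru.end(), 0.0);
      std::fill(jjsr.begin(), jjsr.end(), 0.0);
      double vol = h * h * h;
      for (auto& C : crus) {
        double tot = C.sum_ryr + C.sum_lcc;
        if (tot != 0.0) {
          double v = tot / (cfg.vcyt_frac * C.src_cells.size() * vol);
          for (int idx : C.src_cells) jcru[idx] += v;
        }
        if (C.refill_mean != 0.0) {
          double v = C.vjsr * C.refill_mean /
            (cfg.vsr_frac * C.src_cells.size() * vol);
          for (int idx : C.src_cells) jjsr[idx] += v;
        }
      }
      pde.V = V0;
      res = pde.step(y.data(), ycand.data(), tau, cfg.rtol, cfg.atol,
                     true, cfg.tau_min);
      tm_pde += lap_tm();
      n_rejects += res.n_reject;
      if (res.ok) break;
      stop("PDE step-size underflow at t = %f ms", t);
    }
    double tau_det = res.dt_acc;
    if (tau_det < tau * (1 - 1e-12)) {
      // PDE accepted a smaller step: redo jSR for consistency
      for (auto& C : crus) jsr_integrate(C, tau_det, cfg);
      tm_jsr += lap_tm();
    }
    tau_prop = res.dt_next;
    last_tau_det = tau_det;

    // --- membrane prediction
    lap_tm();
    double V1;
    if (clamp) {
      V1 = interp_wave(wave_t, wave_v, t + tau_det);
    } else {
      for (int i = 0; i < MEM_NY; ++i) memy_pred[i] = memy[i];
      mem_advance(memy_pred, tau_det, cfg.mem_hmax, MP, ical, inaca,
                  istim, c_avg);
      V1 = memy_pred[0];
    }

    tm_mem += lap_tm();
    // --- predicted CRU inputs at t + tau_det
    for (auto& C : crus) {
      double cb = 0.0;
      for (int idx : C.rim_cells) cb += ycand[idx];
      C.cbulk1 = cb / C.rim_cells.size();
      cleft_solve(C, C.cbulk1, C.cjsr_pred, V1, cfg, C.cdi1, false);
    }

    tm_cleft += lap_tm();
    // --- phase A: predict conductance events with a cloned RNG
    std::vector<double> theta(nc, INFINITY);
    int ns = 0;
    {
      std::mt19937_64 rng_copy = rng;
      double dummy_kopen = max_kopen;
      for (int q = 0; q < nc; ++q) {
        // commit = false: gate_cru only reads the clocks
        theta[q] = gate_cru(crus[q], tau_det, V0, V1, crus[q].cjsr,
                            crus[q].cjsr_pred, RP, LP, rng_copy, false,
                            dummy_kopen, nullptr, nullptr, nullptr);
        if (theta[q] < tau_det) ++ns;
      }
    }
    tm_gate += lap_tm();
    double tau_stoc = tau_det;
    if (ns > 0) {
      std::vector<double> tt;
      tt.reserve(ns);
      for (double x : theta) if (x < tau_det) tt.push_back(x);
      std::sort(tt.begin(), tt.end());
      int K = cfg.force_ns1 ? 1 : std::max(1, (int)std::ceil(cfg.cap_frac * ns));
      K = std::min(K, (int)tt.size());
      tau_stoc = tt[K - 1];
    }
    tau_stoc = std::max(tau_stoc, cfg.tau_min);

    // --- re-advance deterministic states to tau_stoc if shorter
    double tau_acc = tau_det;
    double* ynext = ycand.data();
    if (tau_stoc < tau_det * (1 - 1e-12)) {
      for (auto& C : crus) jsr_integrate(C, tau_stoc, cfg);
      std::fill(jcru.begin(), jcru.end(), 0.0);
      std::fill(jjsr.begin(), jjsr.end(), 0.0);
      double vol = h * h * h;
      for (auto& C : crus) {
        double tot = C.sum_ryr + C.sum_lcc;
        if (tot != 0.0) {
          double v = tot / (cfg.vcyt_frac * C.src_cells.size() * vol);
          for (int idx : C.src_cells) jcru[idx] += v;
        }
        if (C.refill_mean != 0.0) {
          double v = C.vjsr * C.refill_mean /
            (cfg.vsr_frac * C.src_cells.size() * vol);
          for (int idx : C.src_cells) jjsr[idx] += v;
        }
      }
      StepResult res2 = pde.step(y.data(), ycand2.data(), tau_stoc,
                                 cfg.rtol, cfg.atol, true, cfg.tau_min);
      if (!res2.ok) stop("PDE step-size underflow at t = %f ms", t);
      n_rejects += res2.n_reject;
      tau_acc = res2.dt_acc;
      if (tau_acc < tau_stoc * (1 - 1e-12))
        for (auto& C : crus) jsr_integrate(C, tau_acc, cfg);
      ynext = ycand2.data();
      if (!clamp) {
        for (int i = 0; i < MEM_NY; ++i) memy_pred[i] = memy[i];
        mem_advance(memy_pred, tau_acc, cfg.mem_hmax, MP, ical, inaca,
                    istim, c_avg);
      }
      V1 = clamp ? interp_wave(wave_t, wave_v, t + tau_acc) : memy_pred[0];
      for (auto& C : crus) {
        double cb = 0.0;
        for (int idx : C.rim_cells) cb += ynext[idx];
        C.cbulk1 = cb / C.rim_cells.size();
        cleft_solve(C, C.cbulk1, C.cjsr_pred, V1, cfg, C.cdi1, false);
      }
    }

    tm_pde += lap_tm();
    // --- phase B: commit gating over the accepted step
    int nev = 0;
    for (int q = 0; q < nc; ++q) {
      std::vector<int> ech, efrom, eto;
      gate_cru(crus[q], tau_acc, V0, V1, crus[q].cjsr, crus[q].cjsr_pred,
               RP, LP, rng, true, max_kopen, &ech, &efrom, &eto);
      nev += ech.size();
      if (cfg.event_log) {
        for (size_t e = 0; e < ech.size(); ++e) {
          if (ev_t.size() < 2000000) {
            ev_t.push_back(t + tau_acc);
            ev_cru.push_back(q + 1);
            ev_ch.push_back(ech[e] + 1);
            ev_from.push_back(efrom[e]);
            ev_to.push_back(eto[e]);
          }
        }
      }
    }
    last_nev = nev;
    tm_gate += lap_tm();

    // --- commit
    std::copy(ynext, ynext + 6 * N, y.begin());
    for (auto& C : crus) C.cjsr = C.cjsr_pred;
    if (!clamp) for (int i = 0; i < MEM_NY; ++i) memy[i] = memy_pred[i];
    jrel_cum += sum_ryr_all * tau_acc / (cfg.omega * cfg.vcyt_frac);
    jca_cum += sum_lcc_all * tau_acc / (cfg.omega * cfg.vcyt_frac);
    t += tau_acc;
    ++n_steps;
    if (n_steps > 50000000L) stop("step budget exceeded");
  }

  NumericVector yout(y.begin(), y.end());
  NumericVector cjsr_out(nc), memout(MEM_NY);
  for (int q = 0; q < nc; ++q) cjsr_out[q] = crus[q].cjsr;
  for (int i = 0; i < MEM_NY; ++i) memout[i] = memy[i];
  List st_out(nc);
  for (int q = 0; q < nc; ++q)
    st_out[q] = IntegerVector(crus[q].st.begin(), crus[q].st.end());
  List events = List::create(
    _["t"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["cru"] = IntegerVector(ev_cru.begin(), ev_cru.end()),
    _["channel"] = IntegerVector(ev_ch.begin(), ev_ch.end()),
    _["from"] = IntegerVector(ev_from.begin(), ev_from.end()),
    _["to"] = IntegerVector(ev_to.begin(), ev_to.end()));
  return List::create(
    _["traces"] = traces, _["y"] = yout, _["cjsr"] = cjsr_out,
    _["mem"] = memout, _["states"] = st_out,
    _["max_kopen"] = max_kopen, _["n_steps"] = (double)n_steps,
    _["n_rejects"] = (double)n_rejects, _["n_lin_it"] = (double)pde.n_lin_it,
    _["timing"] = NumericVector::create(
      _["cleft"] = tm_cleft, _["pde"] = tm_pde, _["gate"] = tm_gate,
      _["jsr"] = tm_jsr, _["mem"] = tm_mem, _["obs"] = tm_obs,
      _["pde_rhs"] = pde.tm_rhs, _["pde_solve"] = pde.tm_solve,
      _["pde_pre"] = pde.tm_pre, _["pde_jv"] = pde.tm_jv,
      _["pde_pc"] = pde.tm_pc, _["n_jv"] = (double)pde.n_jv,
      _["n_rhs"] = (double)pde.n_rhs,
      _["n_solve"] = (double)pde.n_solve,
      _["n_attempt"] = (double)pde.n_attempt),
    _["events"] = events,
    _["snap_c"] = snap_c, _["snap_S"] = snap_S);
}
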