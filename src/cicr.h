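// Shared internals: finite-volume PDE solver (ROS2 + BiCGSTAB),
// channel gating rate laws, and the ventricular membrane ODE model.
#pragma once

#include <RcppArmadillo.h>
#include <cmath>
#include <vector>
#include <random>
#include <algorithm>

// ---------------------------------------------------------------- PDE ----

struct Grid {
  int nx, ny, nz, N;
  double h;
};

struct PdePars {
  double D[6];                       // c, b_tnc, b_cam, b_fluo, S, B_sr
  double kon[3], koff[3], btot[3];   // cytosolic buffers
  double ksr_on, ksr_off, bsr_tot;   // SR buffer
  double pump_vmax, pump_kp;
  bool pump_on, ncx_on, pm_on;
  double g_naca, k_sat, xi, kmnai, kmnao, kmcai, kmcao, c_naca;
  double nai, cao, nao, frt;
  double f_surf, depth;
  std::vector<double> f_cell;        // bulk NCX density factor per cell
  std::vector<int> memb;             // membrane face count per cell
  double vcyt_over_vsr;
};

PdePars unpack_pde(const Rcpp::List& pars, int N);

// NCX base flux (density factor 1), uM/ms; positive = Ca entry
inline double ncx_base(double c_uM, const PdePars& P, double ea, double eb) {
  double c = std::max(c_uM, 1e-9);
  double csm = c * 1e-3;
  double nai3 = P.nai * P.nai * P.nai;
  double nao3 = P.nao * P.nao * P.nao;
  double num = nai3 * P.cao * ea - nao3 * csm * eb;
  double den = (1.0 + P.k_sat * eb) *
    (P.kmcao * nai3 + P.kmnao * P.kmnao * P.kmnao * csm +
     P.kmnai * P.kmnai * P.kmnai * P.cao * (1.0 + csm / P.kmcai) +
     P.kmcai * nao3 * (1.0 + std::pow(P.nai / P.kmnai, 3)) +
     nai3 * P.cao + nao3 * csm);
  double a = P.c_naca / c;
  double allo = 1.0 / (1.0 + a * a * a);
  return P.g_naca * allo * num / den;
}

struct StepResult {
  double dt_acc, dt_next, err;
  int n_reject;
  bool ok;
};

class PdeSolver {
public:
  Grid g;
  PdePars P;
  const double* jcru = nullptr;   // source on c, uM/ms
  const double* jjsr = nullptr;   // sink on S, uM/ms
  double V = -87.0;
  double lin_tol = 1e-6;
  int lin_maxit = 300;
  double gamma = 1.0 + 1.0 / std::sqrt(2.0);
  long n_lin_it = 0;

  void init(const Grid& gg, PdePars&& pp) {
    g = gg; P = std::move(pp);
    int n6 = 6 * g.N;
    blocks.assign(36 * g.N, 0.0);
    pre.assign(36 * g.N, 0.0);
    f0.assign(n6, 0.0); f2.assign(n6, 0.0); lap6.assign(n6, 0.0);
    k1.assign(n6, 0.0); k2.assign(n6, 0.0);
    y2.assign(n6, 0.0);
    wr.assign(n6, 0.0); wrh.assign(n6, 0.0); wp.assign(n6, 0.0);
    wv.assign(n6, 0.0); ws.assign(n6, 0.0); wt.assign(n6, 0.0);
    wz.assign(n6, 0.0); wy.assign(n6, 0.0);
    nbrs.assign(6 * g.N, -1);
    for (int iz = 0; iz < g.nz; ++iz)
      for (int iy = 0; iy < g.ny; ++iy)
        for (int ix = 0; ix < g.nx; ++ix) {
          int i = ix + g.nx * (iy + g.ny * iz);
          nbrs[6 * i + 0] = ix > 0        ? i - 1           : -1;
          nbrs[6 * i + 1] = ix < g.nx - 1 ? i + 1           : -1;
          nbrs[6 * i + 2] = iy > 0        ? i - g.nx        : -1;
          nbrs[6 * i + 3] = iy < g.ny - 1 ? i + g.nx        : -1;
          nbrs[6 * i + 4] = iz > 0        ? i - g.nx * g.ny : -1;
          nbrs[6 * i + 5] = iz < g.nz - 1 ? i + g.nx * g.ny : -1;
        }
  }

  void rhs(const double* y, double* f) const;
  void build_blocks(const double* y);
  // one adaptive ROS2 step; ynew may alias nothing
  StepResult step(const double* y, double* ynew, double dt,
                  double rtol, double atol, bool adaptive,
                  double dt_min = 1e-7);

private:
  std::vector<double> blocks, pre, lap6;
  std::vector<double> f0, f2, k1, k2, y2;
  std::vector<double> wr, wrh, wp, wv, ws, wt, wz, wy;
  std::vector<int> nbrs;

  double lap(const double* u, int i) const {
    const int* nb = &nbrs[6 * i];
    double s = 0.0; double ui = u[i];
    for (int k = 0; k < 6; ++k) if (nb[k] >= 0) s += u[nb[k]] - ui;
    return s / (g.h * g.h);
  }
  int n_nbr(int i) const {
    const int* nb = &nbrs[6 * i];
    int m = 0; for (int k = 0; k < 6; ++k) if (nb[k] >= 0) ++m;
    return m;
  }
  void jv(double gt, const double* v, double* out) const;  // (I - gt J) v
  void lapv(const double* u, double* out) const;           // raw 7-point
  void build_precond(double gt);
  void apply_precond(const double* r, double* z) const;
  bool bicgstab(double gt, const double* b, double* x, double tol,
                int maxit, bool strict, bool warm = false);
  double gt_pre = -1.0;   // gamma*dt the preconditioner was built for
  int pre_age = 1000000;

public:
  // cells carrying point sources this step: excluded from the step-error
  // norm (their sub-grid equilibration transient is source-slaved)
  std::vector<uint8_t> err_skip;
  double tm_rhs = 0, tm_solve = 0, tm_pre = 0;
  double tm_jv = 0, tm_pc = 0;
  long n_rhs = 0, n_solve = 0, n_attempt = 0, n_jv = 0;
};

// ---------------------------------------------------------- gating ----

struct RyrPars {
  int scheme;        // 0 stern4, 1 cannell2, 2 walker2
  double g;          // permeability, um^3/ms
  // stern4
  double kacmax, kinmax, Kac, Kin, kom, kim, Kjsr, lambda;
  // cannell2 (c in mM)
  double Aopen, popen, kopenmax, Aclose, pclose, kclosemax;
  // walker2 (c in uM)
  double kplus, eta, kclose, phib, phik;
};

inline bool ryr_is_open(int scheme, int s) {
  return scheme == 0 ? (s == 1) : (s == 1);
}

// exit rates from state s at (cdi, cjsr); returns count, fills rates/dests
inline int ryr_exits(int s, double cdi, double cjsr, const RyrPars& p,
                     double* r, int* d) {
  if (p.scheme == 0) {           // stern4: 0 R, 1 O, 2 I, 3 RI
    double fj = cjsr / (cjsr + p.Kjsr);
    double c4 = cdi * cdi * cdi * cdi;
    double K4 = p.Kac * p.Kac * p.Kac * p.Kac;
    double ko = p.kacmax * c4 / (K4 + c4) * fj;
    double ki = p.kinmax * cdi / (p.Kin + cdi);
    switch (s) {
    case 0: r[0] = ko; d[0] = 1; r[1] = ki; d[1] = 3; return 2;
    case 1: r[0] = p.kom; d[0] = 0; r[1] = ki * p.lambda; d[1] = 2; return 2;
    case 2: r[0] = p.kim; d[0] = 1; r[1] = p.kom; d[1] = 3; return 2;
    default: r[0] = p.kim; d[0] = 0; r[1] = ko; d[1] = 2; return 2;
    }
  }
  if (p.scheme == 1) {           // cannell2: 0 C, 1 O; laws in mM
    double cm = cdi * 1e-3;
    if (s == 0) {
      double k = cm > 0 ? std::min(p.Aopen * std::pow(cm, p.popen),
                                   p.kopenmax) : 0.0;
      r[0] = k; d[0] = 1; return 1;
    }
    double k = cm > 0 ? std::min(p.Aclose * std::pow(cm, p.pclose),
                                 p.kclosemax) : p.kclosemax;
    r[0] = k; d[0] = 0; return 1;
  }
  // walker2: 0 C, 1 O
  if (s == 0) {
    double phi = p.phib + std::pow(cjsr / p.phik, 4);
    r[0] = p.kplus * phi * std::pow(std::max(cdi, 0.0), p.eta);
    d[0] = 1; return 1;
  }
  r[0] = p.kclose; d[0] = 0; return 1;
}

struct LccPars {
  double JL, kp0, cpbar, taupo, r1, r2, s1p, k1p, k2, k21p, Tba;
};

// voltage-dependent shared context
struct LccCtx {
  double alpha, beta, Ps, k3, k5p, k6p, k4fac, k4pfac, s2, s2p;
};

inline void lcc_ctx(double V, const LccPars& p, LccCtx& c) {
  const double s1bar = 0.0182688, k1bar = 0.024168;
  double poinf = 1.0 / (1.0 + std::exp(-V / 8.0));
  c.alpha = poinf / p.taupo;
  c.beta = std::max(1.0 - poinf, 1e-12) / p.taupo;
  c.Ps = 1.0 / (1.0 + std::exp(-(V + 40.0) / 11.32));
  double e3 = std::exp(-(V + 40.0) / 3.0);
  c.k3 = e3 / (3.0 * (1.0 + e3));
  c.k5p = (1.0 - c.Ps) / p.Tba;
  c.k6p = c.Ps / p.Tba;
  double oPs = std::max(c.Ps, 1e-12);
  c.k4fac = c.k3 * (c.alpha / c.beta) * (k1bar / p.k2) *
    ((1.0 - c.Ps) / oPs);
  c.k4pfac = c.k3 * (c.alpha / c.beta) * (p.k1p / p.k21p) *
    ((1.0 - c.Ps) / oPs);
  c.s2 = (s1bar / k1bar) * p.k2 * (p.r1 / p.r2);
  c.s2p = p.s1p * (p.k21p / p.k1p) * (p.r1 / p.r2);
}

// states: 0 C2, 1 C1, 2 O, 3 I1Ca, 4 I2Ca, 5 I1Ba, 6 I2Ba
inline bool lcc_is_open(int s) { return s == 2; }

inline int lcc_exits(int s, double cp, const LccPars& p, const LccCtx& c,
                     double* r, int* d) {
  const double s1bar = 0.0182688, k1bar = 0.024168;
  double cc = std::max(cp, 1e-9);
  double a = p.kp0 / cc;
  double fcp = 1.0 / (1.0 + a * a * a);
  double u = std::pow(cc / p.cpbar, 4);
  double tca = (78.0329 + 0.1 * u) / (1.0 + u);
  switch (s) {
  case 0:  // C2
    r[0] = c.alpha; d[0] = 1;
    r[1] = fcp * c.Ps / tca; d[1] = 4;
    r[2] = c.k6p; d[2] = 6;
    return 3;
  case 1:  // C1
    r[0] = c.beta; d[0] = 0;
    r[1] = p.r1; d[1] = 2;
    r[2] = k1bar * fcp; d[2] = 3;
    r[3] = p.k1p; d[3] = 5;
    return 4;
  case 2:  // O
    r[0] = p.r2; d[0] = 1;
    r[1] = s1bar * fcp; d[1] = 3;
    r[2] = p.s1p; d[2] = 5;
    return 3;
  case 3:  // I1Ca
    r[0] = p.k2; d[0] = 1;
    r[1] = c.s2; d[1] = 2;
    r[2] = c.k3; d[2] = 4;
    return 3;
  case 4:  // I2Ca
    r[0] = (1.0 - c.Ps) / tca; d[0] = 0;
    r[1] = c.k4fac; d[1] = 3;
    return 2;
  case 5:  // I1Ba
    r[0] = p.k21p; d[0] = 1;
    r[1] = c.s2p; d[1] = 2;
    r[2] = c.k3; d[2] = 6;
    return 3;
  default: // I2Ba
    r[0] = c.k5p; d[0] = 0;
    r[1] = c.k4pfac; d[1] = 5;
    return 2;
  }
}

// ---------------------------------------------------------- membrane ----

// state: 0 V, 1 m, 2 h, 3 j, 4 xr, 5 xs1, 6 xs2, 7 xtos, 8 ytos,
//        9 xtof, 10 ytof
constexpr int MEM_NY = 11;

struct MemPars {
  double gna, gtof, gtos, gk1, gkr, gks, gnak;
  double nao, ki, ko, nai, frt;
};

struct MemCurrents {
  double ina, ik1, ikr, iks, itof, itos, inak;
};

void mem_derivs(const double* y, const MemPars& M, double ical,
                double inaca, double istim, double ci_uM, double* dy,
                MemCurrents* out);
void mem_gates_inf(double V, const MemPars& M, double* y);
void mem_advance(double* y, double dt, double hmax, const MemPars& M,
                 double ical, double inaca, double istim, double ci_uM);
MemPars unpack_mem(const Rcpp::List& pars);
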