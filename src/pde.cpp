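// Finite-volume bidomain reaction-diffusion kernel: right-hand side,
// analytic reaction Jacobian blocks, matrix-free BiCGSTAB with per-cell
// block-Jacobi preconditioning, and the two-stage L-stable Rosenbrock
// step with embedded error control.
#include "cicr.h"
#include <chrono>
// [[Rcpp::depends(RcppArmadillo)]]
using stclk = std::chrono::steady_clock;
static inline double secs(stclk::time_point a, stclk::time_point b) {
  return std::chrono::duration<double>(b - a).count();
}

using namespace Rcpp;

PdePars unpack_pde(const List& pars, int N) {
  PdePars P;
  NumericVector D = pars["D"], kon = pars["kon"], koff = pars["koff"],
    btot = pars["btot"];
  for (int k = 0; k < 6; ++k) P.D[k] = D[k];
  for (int k = 0; k < 3; ++k) {
    P.kon[k] = kon[k]; P.koff[k] = koff[k]; P.btot[k] = btot[k];
  }
  P.ksr_on = pars["ksr_on"]; P.ksr_off = pars["ksr_off"];
  P.bsr_tot = pars["bsr_tot"];
  P.pump_vmax = pars["pump_vmax"]; P.pump_kp = pars["pump_kp"];
  P.pump_on = as<int>(pars["pump_on"]) != 0;
  P.ncx_on = as<int>(pars["ncx_on"]) != 0;
  P.pm_on = as<int>(pars["pm_on"]) != 0;
  P.g_naca = pars["g_naca"]; P.k_sat = pars["k_sat"]; P.xi = pars["xi"];
  P.kmnai = pars["kmnai"]; P.kmnao = pars["kmnao"];
  P.kmcai = pars["kmcai"]; P.kmcao = pars["kmcao"];
  P.c_naca = pars["c_naca"]; P.nai = pars["nai"];
  P.cao = pars["cao"]; P.nao = pars["nao"]; P.frt = pars["frt"];
  P.f_surf = pars["f_surf"]; P.depth = pars["depth"];
  NumericVector fc = pars["f_cell"];
  IntegerVector mb = pars["memb"];
  if ((int)fc.size() != N || (int)mb.size() != N)
    stop("f_cell/memb length mismatch");
  P.f_cell.assign(fc.begin(), fc.end());
  P.memb.assign(mb.begin(), mb.end());
  P.vcyt_over_vsr = pars["vcyt_over_vsr"];
  return P;
}

// raw 7-point no-flux Laplacian of one field (not yet scaled by 1/h^2)
void PdeSolver::lapv(const double* u, double* out) const {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      const double* row = u + (size_t)nx * (iy + (size_t)ny * iz);
      double* orow = out + (size_t)nx * (iy + (size_t)ny * iz);
      for (int ix = 0; ix < nx; ++ix) {
        double s = 0.0;
        if (ix > 0) s += row[ix - 1] - row[ix];
        if (ix < nx - 1) s += row[ix + 1] - row[ix];
        orow[ix] = s;
      }
      if (iy > 0) {
        const double* p = row - nx;
        for (int ix = 0; ix < nx; ++ix) orow[ix] += p[ix] - row[ix];
      }
      if (iy < ny - 1) {
        const double* p = row + nx;
        for (int ix = 0; ix < nx; ++ix) orow[ix] += p[ix] - row[ix];
      }
      if (iz > 0) {
        const double* p = row - (size_t)nx * ny;
        for (int ix = 0; ix < nx; ++ix) orow[ix] += p[ix] - row[ix];
      }
      if (iz < nz - 1) {
        const double* p = row + (size_t)nx * ny;
        for (int ix = 0; ix < nx; ++ix) orow[ix] += p[ix] - row[ix];
      }
    }
}

void PdeSolver::rhs(const double* y, double* f) const {
  const int N = g.N;
  const double ih2 = 1.0 / (g.h * g.h);
  double* lp = const_cast<double*>(lap6.data());
  for (int ff = 0; ff < 6; ++ff) {
    if (P.D[ff] > 0) lapv(y + ff * N, lp + ff * N);
    else std::fill(lp + ff * N, lp + (ff + 1) * N, 0.0);
  }
  const double* c = y;
  const double* S = y + 4 * N;
  const double* Bs = y + 5 * N;
  double ea = std::exp(P.xi * V * P.frt);
  double eb = std::exp((P.xi - 1.0) * V * P.frt);
  for (int i = 0; i < N; ++i) {
    double ci = c[i];
    double R[3];
    for (int k = 0; k < 3; ++k) {
      double b = y[(k + 1) * N + i];
      R[k] = P.kon[k] * (P.btot[k] - b) * ci - P.koff[k] * b;
      f[(k + 1) * N + i] = P.D[k + 1] * ih2 * lp[(k + 1) * N + i] + R[k];
    }
    double jp = 0.0;
    if (P.pump_on) {
      double c2 = ci * ci;
      jp = P.pump_vmax * c2 / (P.pump_kp * P.pump_kp + c2);
    }
    double jn = 0.0, jpm = 0.0;
    if (P.ncx_on) {
      double base = ncx_base(ci, P, ea, eb);
      jn = P.f_cell[i] * base;
      if (P.pm_on && P.memb[i] > 0)
        jpm = P.memb[i] * P.f_surf * base * P.depth / g.h;
    }
    f[i] = P.D[0] * ih2 * lp[i] + jcru[i] + jn + jpm - jp -
      (R[0] + R[1] + R[2]);
    double Rsr = P.ksr_on * (P.bsr_tot - Bs[i]) * S[i] - P.ksr_off * Bs[i];
    f[4 * N + i] = P.D[4] * ih2 * lp[4 * N + i] - Rsr - jjsr[i] +
      P.vcyt_over_vsr * jp;
    f[5 * N + i] = P.D[5] * ih2 * lp[5 * N + i] + Rsr;
  }
}

void PdeSolver::build_blocks(const double* y) {
  const int N = g.N;
  for (int i = 0; i < N; ++i) {
    double* B = &blocks[36 * i];
    std::fill(B, B + 36, 0.0);
    double ci = y[i];
    double dsum = 0.0;
    for (int k = 0; k < 3; ++k) {
      double b = y[(k + 1) * N + i];
      double dRdc = P.kon[k] * (P.btot[k] - b);
      double dRdb = -(P.kon[k] * ci + P.koff[k]);
      B[0 * 6 + (k + 1)] = -dRdb;           // d(dc)/db_k = +kon c + koff
      B[(k + 1) * 6 + 0] = dRdc;
      B[(k + 1) * 6 + (k + 1)] = dRdb;
      dsum += dRdc;
    }
    double dpump = 0.0;
    if (P.pump_on) {
      double den = P.pump_kp * P.pump_kp + ci * ci;
      dpump = P.pump_vmax * 2.0 * ci * P.pump_kp * P.pump_kp / (den * den);
    }
    B[0] = -dpump - dsum;
    double Si = y[4 * N + i], Bsi = y[5 * N + i];
    double dRsrdS = P.ksr_on * (P.bsr_tot - Bsi);
    double dRsrdB = -(P.ksr_on * Si + P.ksr_off);
    B[4 * 6 + 0] = P.vcyt_over_vsr * dpump;
    B[4 * 6 + 4] = -dRsrdS;
    B[4 * 6 + 5] = -dRsrdB;
    B[5 * 6 + 4] = dRsrdS;
    B[5 * 6 + 5] = dRsrdB;
  }
}

// out = (I - gt J) v,  J = diffusion + reaction blocks
void PdeSolver::jv(double gt, const double* v, double* out) const {
  const int N = g.N;
  const double ih2 = 1.0 / (g.h * g.h);
  for (int ff = 0; ff < 6; ++ff) {
    const double* vf = v + ff * N;
    double* of = out + ff * N;
    double Df = P.D[ff];
    if (Df > 0) {
      lapv(vf, of);
      double sc = -gt * Df * ih2;
      for (int i = 0; i < N; ++i) of[i] *= sc;
    } else {
      std::fill(of, of + N, 0.0);
    }
  }
  for (int i = 0; i < N; ++i) {
    const double* B = &blocks[36 * i];
    double vi[6];
    for (int ff = 0; ff < 6; ++ff) vi[ff] = v[ff * N + i];
    for (int ff = 0; ff < 6; ++ff) {
      double s = 0.0;
      const double* Br = B + 6 * ff;
      for (int k = 0; k < 6; ++k) s += Br[k] * vi[k];
      out[ff * N + i] += vi[ff] - gt * s;
    }
  }
}

// invert (I - gt (B_cell + diag(lap_diag))) per cell
void PdeSolver::build_precond(double gt) {
  const int N = g.N;
  for (int i = 0; i < N; ++i) {
    double M[36];
    const double* B = &blocks[36 * i];
    double ld = -n_nbr(i) / (g.h * g.h);
    for (int r = 0; r < 6; ++r)
      for (int cc = 0; cc < 6; ++cc) {
        double v = -gt * B[6 * r + cc];
        if (r == cc) v += 1.0 - gt * P.D[r] * ld;
        M[6 * r + cc] = v;
      }
    // Gauss-Jordan inverse of the 6x6
    double* inv = &pre[36 * i];
    double aug[6][12];
    for (int r = 0; r < 6; ++r) {
      for (int cc = 0; cc < 6; ++cc) { aug[r][cc] = M[6 * r + cc]; aug[r][6 + cc] = (r == cc); }
    }
    for (int col = 0; col < 6; ++col) {
      int piv = col;
      for (int r = col + 1; r < 6; ++r)
        if (std::fabs(aug[r][col]) > std::fabs(aug[piv][col])) piv = r;
      if (std::fabs(aug[piv][col]) < 1e-300) { aug[piv][col] = 1e-300; }
      if (piv != col) for (int cc = 0; cc < 12; ++cc) std::swap(aug[piv][cc], aug[col][cc]);
      double d = aug[col][col];
      for (int cc = 0; cc < 12; ++cc) aug[col][cc] /= d;
      for (int r = 0; r < 6; ++r) {
        if (r == col) continue;
        double fct = aug[r][col];
        if (fct == 0.0) continue;
        for (int cc = 0; cc < 12; ++cc) aug[r][cc] -= fct * aug[col][cc];
      }
    }
    for (int r = 0; r < 6; ++r)
      for (int cc = 0; cc < 6; ++cc) inv[6 * r + cc] = aug[r][6 + cc];
  }
}

void PdeSolver::apply_precond(const double* r, double* z) const {
  const int N = g.N;
  for (int i = 0; i < N; ++i) {
    const double* inv = &pre[36 * i];
    double ri[6];
    for (int ff = 0; ff < 6; ++ff) ri[ff] = r[ff * N + i];
    for (int ff = 0; ff < 6; ++ff) {
      double s = 0.0;
      const double* row = inv + 6 * ff;
      for (int k = 0; k < 6; ++k) s += row[k] * ri[k];
      z[ff * N + i] = s;
    }
  }
}

static inline double dot(const std::vector<double>& a,
                         const std::vector<double>& b) {
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) s += a[i] * b[i];
  return s;
}

// solve (I - gt J) x = b ; x initialized to 0 by caller convention.
// strict = false tolerates running out of iterations (approximate solve).
bool PdeSolver::bicgstab(double gt, const double* b, double* x, double tol_rel,
                         int maxit, bool strict, bool warm) {
  const int n6 = 6 * g.N;
  double bnrm = 0.0;
  for (int i = 0; i < n6; ++i) bnrm += b[i] * b[i];
  bnrm = std::sqrt(bnrm);
  if (bnrm == 0.0) { std::fill(x, x + n6, 0.0); return true; }
  if (warm) {
    // initial guess from the previous step's stage vector
    jv(gt, x, wr.data());
    double rn = 0.0;
    for (int i = 0; i < n6; ++i) { wr[i] = b[i] - wr[i]; rn += wr[i] * wr[i]; }
    if (std::sqrt(rn) <= tol_rel * bnrm) return true;
  } else {
    std::fill(x, x + n6, 0.0);
    for (int i = 0; i < n6; ++i) wr[i] = b[i];
  }
  wrh = wr;
  double rho = 1.0, alpha = 1.0, omega = 1.0;
  std::fill(wp.begin(), wp.end(), 0.0);
  std::fill(wv.begin(), wv.end(), 0.0);
  double tol = tol_rel * bnrm;
  for (int it = 0; it < maxit; ++it) {
    double rho1 = dot(wrh, wr);
    if (std::fabs(rho1) < 1e-300) return false;
    if (it == 0) {
      wp = wr;
    } else {
      double beta = (rho1 / rho) * (alpha / omega);
      for (int i = 0; i < n6; ++i)
        wp[i] = wr[i] + beta * (wp[i] - omega * wv[i]);
    }
    rho = rho1;
    auto tq = stclk::now();
    apply_precond(wp.data(), wy.data());
    tm_pc += secs(tq, stclk::now()); tq = stclk::now();
    jv(gt, wy.data(), wv.data());
    tm_jv += secs(tq, stclk::now()); ++n_jv;
    double rhv = dot(wrh, wv);
    if (std::fabs(rhv) < 1e-300) return false;
    alpha = rho / rhv;
    for (int i = 0; i < n6; ++i) ws[i] = wr[i] - alpha * wv[i];
    double snrm = std::sqrt(dot(ws, ws));
    ++n_lin_it;
    if (snrm < tol) {
      for (int i = 0; i < n6; ++i) x[i] += alpha * wy[i];
      return true;
    }
    auto tq2 = stclk::now();
    apply_precond(ws.data(), wz.data());
    tm_pc += secs(tq2, stclk::now()); tq2 = stclk::now();
    jv(gt, wz.data(), wt.data());
    tm_jv += secs(tq2, stclk::now()); ++n_jv;
    double tt = dot(wt, wt);
    if (tt < 1e-300) return false;
    omega = dot(wt, ws) / tt;
    for (int i = 0; i < n6; ++i) {
      x[i] += alpha * wy[i] + omega * wz[i];
      wr[i] = ws[i] - omega * wt[i];
    }
    double rnrm = std::sqrt(dot(wr, wr));
    if (rnrm < tol) return true;
    if (std::fabs(omega) < 1e-300) return false;
  }
  return !strict;
}

StepResult PdeSolver::step(const double* y, double* ynew, double dt,
                           double rtol, double atol, bool adaptive,
                           double dt_min) {
  const int n6 = 6 * g.N;
  StepResult res{0.0, dt, 0.0, 0, false};
  auto t0 = stclk::now();
  rhs(y, f0.data());
  build_blocks(y);
  tm_rhs += secs(t0, stclk::now()); ++n_rhs;
  for (int attempt = 0; attempt < 40; ++attempt) {
    double gt = gamma * dt;
    // the block-Jacobi preconditioner tolerates staleness: rebuild only
    // when the stage factor drifts or periodically
    ++n_attempt;
    if (gt_pre <= 0 || std::fabs(gt - gt_pre) > 0.25 * gt_pre ||
        pre_age >= 25) {
      auto tp = stclk::now();
      build_precond(gt);
      tm_pre += secs(tp, stclk::now());
      gt_pre = gt; pre_age = 0;
    }
    ++pre_age;
    auto ts = stclk::now();
    bool ok1 = bicgstab(gt, f0.data(), k1.data(), lin_tol, lin_maxit, true,
                  true);
    tm_solve += secs(ts, stclk::now()); ++n_solve;
    if (!ok1) {
      dt *= 0.5; ++res.n_reject;
      if (dt < dt_min) return res;
      continue;
    }
    for (int i = 0; i < n6; ++i) y2[i] = y[i] + dt * k1[i];
    auto tr2 = stclk::now();
    rhs(y2.data(), f2.data());
    tm_rhs += secs(tr2, stclk::now()); ++n_rhs;
    for (int i = 0; i < n6; ++i) f2[i] -= 2.0 * k1[i];
    ts = stclk::now();
    bool ok2 = bicgstab(gt, f2.data(), k2.data(), lin_tol, lin_maxit, true,
                  true);
    tm_solve += secs(ts, stclk::now()); ++n_solve;
    if (!ok2) {
      dt *= 0.5; ++res.n_reject;
      if (dt < dt_min) return res;
      continue;
    }
    // raw estimate = difference to the embedded first-order solution;
    // filter it through (I - gt J)^-1 so stiff modes handled exactly by
    // the L-stable scheme do not throttle the step
    for (int i = 0; i < n6; ++i) f2[i] = 0.5 * dt * (k1[i] + k2[i]);
    // the filter only needs ~5% accuracy: it damps stiff components,
    // it does not enter the solution
    ts = stclk::now();
    if (!bicgstab(gt, f2.data(), y2.data(), 0.05, 12, false)) {
      std::copy(f2.begin(), f2.end(), y2.begin());
    }
    tm_solve += secs(ts, stclk::now()); ++n_solve;
    // weighted RMS norm: the error of a switching point source is
    // confined to a few cells and should not throttle the global step
    double err2 = 0.0;
    double ymin = 0.0;
    bool skip_on = !err_skip.empty();
    for (int i = 0; i < n6; ++i) {
      double yn = y[i] + dt * (1.5 * k1[i] + 0.5 * k2[i]);
      ynew[i] = yn;
      if (skip_on && err_skip[i % g.N]) { if (yn < ymin) ymin = yn; continue; }
      double w = atol + rtol * std::fabs(y[i]);
      double ew = y2[i] / w;
      err2 += ew * ew;
      if (yn < ymin) ymin = yn;
    }
    double err = std::sqrt(err2 / n6);
    bool neg_bad = ymin < -100.0 * atol;
    if (!adaptive || (err <= 1.0 && !neg_bad)) {
      for (int i = 0; i < n6; ++i) if (ynew[i] < 0.0) ynew[i] = 0.0;
      res.dt_acc = dt;
      res.err = err;
      // conservative growth to avoid accept/reject ping-pong
      double fac = err > 0 ? 0.8 / std::sqrt(err) : 2.0;
      fac = std::min(2.0, std::max(0.2, fac));
      if (res.n_reject > 0) fac = std::min(fac, 1.0);
      res.dt_next = dt * fac;
      res.ok = true;
      return res;
    }
    ++res.n_reject;
    double fac = err > 0 ? 0.9 / std::sqrt(err) : 0.5;
    fac = std::min(0.5, std::max(0.02, fac));
    if (neg_bad) fac = std::min(fac, 0.3);
    dt *= fac;
    if (dt < dt_min) return res;
  }
  return res;
}

// [[Rcpp::export]]
List pde_step_cpp(NumericVector y, IntegerVector dims, double h,
                  List pars, NumericVector jcru, NumericVector jjsr,
                  double V, double dt, double rtol, double atol,
                  double lin_tol, bool adaptive) {
  Grid g{dims[0], dims[1], dims[2], dims[0] * dims[1] * dims[2], h};
  if ((int)y.size() != 6 * g.N) stop("state length mismatch");
  PdeSolver s;
  s.init(g, unpack_pde(pars, g.N));
  s.jcru = jcru.begin();
  s.jjsr = jjsr.begin();
  s.V = V;
  s.lin_tol = lin_tol;
  NumericVector out(6 * g.N);
  StepResult r = s.step(y.begin(), out.begin(), dt, rtol, atol, adaptive);
  return List::create(_["y"] = out, _["dt_accepted"] = r.ok ? r.dt_acc : 0.0,
                      _["dt_next"] = r.dt_next, _["err"] = r.err,
                      _["n_reject"] = r.n_reject);
}
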