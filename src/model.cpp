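// Rabbit ventricular membrane model: fast Na+ current, K+ currents,
// Na+/K+ pump, and Hodgkin-Huxley-type gate kinetics. The L-type Ca2+
// current and the Na+/Ca2+-exchanger current are supplied externally
// (they are computed from the CRU ensemble and the bulk fields).
#include "cicr.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double ratefn(double x, double num, double expc) {
  // num * x / (1 - exp(-expc * x)) with the x -> 0 limit
  double d = 1.0 - std::exp(-expc * x);
  if (std::fabs(d) < 1e-9) return num / expc;
  return num * x / d;
}
static inline double ratefn2(double x, double num, double expc) {
  // num * x / (exp(expc * x) - 1) with the x -> 0 limit
  double d = std::exp(expc * x) - 1.0;
  if (std::fabs(d) < 1e-9) return num / expc;
  return num * x / d;
}

void mem_derivs(const double* y, const MemPars& M, double ical,
                double inaca, double istim, double ci_uM, double* dy,
                MemCurrents* out) {
  const double V = y[0];
  const double m = y[1], hh = y[2], jj = y[3];
  const double xr = y[4], xs1 = y[5], xs2 = y[6];
  const double xtos = y[7], ytos = y[8], xtof = y[9], ytof = y[10];
  const double ena = std::log(M.nao / M.nai) / M.frt;
  const double ek = std::log(M.ko / M.ki) / M.frt;
  const double prnak = 0.01833;
  const double eks = std::log((M.ko + prnak * M.nao) /
                              (M.ki + prnak * M.nai)) / M.frt;

  // fast Na+
  double ina = M.gna * m * m * m * hh * jj * (V - ena);
  double am = ratefn(V + 47.13, 0.32, 0.1);
  double bm = 0.08 * std::exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / -11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) /
      (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp((80.0 + V) / -6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) -
          3.474e-5 * std::exp(-0.04391 * V)) * (V + 37.78) /
      (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) /
      (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }

  // rapid delayed rectifier
  double xr_inf = 1.0 / (1.0 + std::exp(-(V + 50.0) / 7.5));
  double txr = 1.0 / (ratefn(V + 7.0, 0.00138, 0.123) +
                      ratefn2(V + 10.0, 0.00061, 0.145));
  double rkr = 1.0 / (1.0 + std::exp((V + 33.0) / 22.4));
  double ikr = M.gkr * std::sqrt(M.ko / 5.4) * xr * rkr * (V - ek);

  // slow delayed rectifier with Ca2+-sensitive conductance factor
  double xs_inf = 1.0 / (1.0 + std::exp(-(V - 1.5) / 16.7));
  double txs1 = 1.0 / (ratefn(V + 30.0, 7.19e-5, 0.148) +
                       ratefn2(V + 30.0, 1.31e-4, 0.0687));
  double txs2 = 4.0 * txs1;
  double ci = std::max(ci_uM, 1e-6);
  double qks = 1.0 + 0.8 / (1.0 + std::pow(0.5 / ci, 3));
  double iks = M.gks * qks * xs1 * xs2 * (V - eks);

  // transient outward
  double xto_inf = 1.0 / (1.0 + std::exp(-(V + 3.0) / 15.0));
  double yto_inf = 1.0 / (1.0 + std::exp((V + 33.5) / 10.0));
  double rs_inf = yto_inf;
  double txtos = 9.0 / (1.0 + std::exp((V + 3.0) / 15.0)) + 0.5;
  double tytos = 3000.0 / (1.0 + std::exp((V + 60.0) / 10.0)) + 30.0;
  double txtof = 3.5 * std::exp(-(V / 30.0) * (V / 30.0)) + 1.5;
  double tytof = 20.0 / (1.0 + std::exp((V + 33.5) / 10.0)) + 20.0;
  double itos = M.gtos * xtos * (ytos + 0.5 * rs_inf) * (V - ek);
  double itof = M.gtof * xtof * ytof * (V - ek);

  // inward rectifier
  double aki = 1.02 / (1.0 + std::exp(0.2385 * (V - ek - 59.215)));
  double bki = (0.49124 * std::exp(0.08032 * (V - ek + 5.476)) +
                std::exp(0.06175 * (V - ek - 594.31))) /
    (1.0 + std::exp(-0.5143 * (V - ek + 4.753)));
  double ik1 = M.gk1 * std::sqrt(M.ko / 5.4) * aki / (aki + bki) * (V - ek);

  // Na+/K+ pump
  double sigma = (std::exp(M.nao / 67.3) - 1.0) / 7.0;
  double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V * M.frt) +
                       0.0365 * sigma * std::exp(-V * M.frt));
  double inak = M.gnak * fnak * M.ko / (M.ko + 1.5) *
    M.nai / (M.nai + 12.0);

  double iion = ina + ik1 + ikr + iks + itof + itos + inak + ical + inaca;
  dy[0] = -(iion + istim);
  dy[1] = am * (1.0 - m) - bm * m;
  dy[2] = ah * (1.0 - hh) - bh * hh;
  dy[3] = aj * (1.0 - jj) - bj * jj;
  dy[4] = (xr_inf - xr) / txr;
  dy[5] = (xs_inf - xs1) / txs1;
  dy[6] = (xs_inf - xs2) / txs2;
  dy[7] = (xto_inf - xtos) / txtos;
  dy[8] = (yto_inf - ytos) / tytos;
  dy[9] = (xto_inf - xtof) / txtof;
  dy[10] = (yto_inf - ytof) / tytof;
  if (out) {
    out->ina = ina; out->ik1 = ik1; out->ikr = ikr; out->iks = iks;
    out->itof = itof; out->itos = itos; out->inak = inak;
  }
}

void mem_gates_inf(double V, const MemPars& M, double* y) {
  double dy[MEM_NY];
  // iterate: gate steady states from the alpha/beta at V
  double am = ratefn(V + 47.13, 0.32, 0.1);
  double bm = 0.08 * std::exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / -11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) /
      (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp((80.0 + V) / -6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) -
          3.474e-5 * std::exp(-0.04391 * V)) * (V + 37.78) /
      (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) /
      (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  y[0] = V;
  y[1] = am / (am + bm);
  y[2] = (ah + bh) > 0 ? ah / (ah + bh) : 1.0;
  y[3] = (aj + bj) > 0 ? aj / (aj + bj) : 1.0;
  y[4] = 1.0 / (1.0 + std::exp(-(V + 50.0) / 7.5));
  y[5] = y[6] = 1.0 / (1.0 + std::exp(-(V - 1.5) / 16.7));
  y[7] = y[9] = 1.0 / (1.0 + std::exp(-(V + 3.0) / 15.0));
  y[8] = y[10] = 1.0 / (1.0 + std::exp((V + 33.5) / 10.0));
  (void)dy;
}

void mem_advance(double* y, double dt, double hmax, const MemPars& M,
                 double ical, double inaca, double istim, double ci_uM) {
  int nsub = std::max(1, (int)std::ceil(dt / hmax));
  double h = dt / nsub;
  double k1[MEM_NY], k2[MEM_NY], k3[MEM_NY], k4[MEM_NY], tmp[MEM_NY];
  for (int s = 0; s < nsub; ++s) {
    mem_derivs(y, M, ical, inaca, istim, ci_uM, k1, nullptr);
    for (int i = 0; i < MEM_NY; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
    mem_derivs(tmp, M, ical, inaca, istim, ci_uM, k2, nullptr);
    for (int i = 0; i < MEM_NY; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
    mem_derivs(tmp, M, ical, inaca, istim, ci_uM, k3, nullptr);
    for (int i = 0; i < MEM_NY; ++i) tmp[i] = y[i] + h * k3[i];
    mem_derivs(tmp, M, ical, inaca, istim, ci_uM, k4, nullptr);
    for (int i = 0; i < MEM_NY; ++i)
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (int i = 1; i < MEM_NY; ++i)
      y[i] = std::min(1.0, std::max(0.0, y[i]));
  }
}

MemPars unpack_mem(const List& pars) {
  MemPars M;
  M.gna = pars["g_na"]; M.gtof = pars["g_tof"]; M.gtos = pars["g_tos"];
  M.gk1 = pars["g_k1"]; M.gkr = pars["g_kr"]; M.gks = pars["g_ks"];
  M.gnak = pars["g_nak"];
  M.nao = pars["na_o"]; M.ki = pars["k_i"]; M.ko = pars["k_o"];
  M.nai = pars["nai"]; M.frt = pars["frt"];
  return M;
}

// [[Rcpp::export]]
List mahajan_currents_cpp(NumericVector y, List pars, double ical,
                          double inaca, double ci) {
  if (y.size() != MEM_NY) stop("membrane state must have 11 components");
  MemPars M = unpack_mem(pars);
  double dy[MEM_NY];
  MemCurrents cur;
  mem_derivs(y.begin(), M, ical, inaca, 0.0, ci, dy, &cur);
  return List::create(
    _["dVdt"] = dy[0], _["i_na"] = cur.ina, _["i_k1"] = cur.ik1,
    _["i_kr"] = cur.ikr, _["i_ks"] = cur.iks, _["i_tof"] = cur.itof,
    _["i_tos"] = cur.itos, _["i_nak"] = cur.inak);
}

// [[Rcpp::export]]
NumericVector mahajan_step_cpp(NumericVector y, List pars, double dt,
                               double hmax, double ical, double inaca,
                               double istim, double ci) {
  if (y.size() != MEM_NY) stop("membrane state must have 11 components");
  MemPars M = unpack_mem(pars);
  NumericVector out = clone(y);
  mem_advance(out.begin(), dt, hmax, M, ical, inaca, istim, ci);
  return out;
}

// [[Rcpp::export]]
NumericVector mahajan_init_cpp(double V, List pars) {
  MemPars M = unpack_mem(pars);
  NumericVector y(MEM_NY);
  mem_gates_inf(V, M, y.begin());
  return y;
}
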