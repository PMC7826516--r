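// Molecular-mechanics evaluator: harmonic bonds/angles, cosine torsions,
// 12-6 Lennard-Jones with exclusions and scaled 1-4 pairs, optional fixed
// point-charge Coulomb. Returns total energy, per-term totals, an exact
// per-atom energy partition (bond 1/2 each, angle 1/3, torsion 1/4,
// pair 1/2), and optionally the analytic gradient.
#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// [[Rcpp::export]]
List ff_eval_cpp(NumericMatrix pos,
                 IntegerVector bi, IntegerVector bj,
                 NumericVector bk, NumericVector br0,
                 IntegerVector ai, IntegerVector aj, IntegerVector ak,
                 NumericVector akf, NumericVector at0,
                 IntegerVector ti, IntegerVector tj,
                 IntegerVector tk, IntegerVector tl,
                 NumericVector tv, IntegerVector tn, NumericVector tg,
                 NumericVector eps, NumericVector sig,
                 IntegerVector exi, IntegerVector exj,
                 IntegerVector p14i, IntegerVector p14j, double scale14,
                 double cutoff, NumericVector q, double kcoul,
                 bool want_grad) {
  const int n = pos.nrow();
  NumericVector per(n);
  NumericMatrix grad(want_grad ? n : 1, 3);
  double e_bond = 0, e_angle = 0, e_tors = 0, e_vdw = 0, e_coul = 0;
  const double* P = REAL(pos);           // column-major: x at P[i], y P[i+n]
  auto px = [&](int i) { return P[i]; };
  auto py = [&](int i) { return P[i + n]; };
  auto pz = [&](int i) { return P[i + 2 * n]; };
  double* G = want_grad ? REAL(grad) : nullptr;
  const int gn = want_grad ? n : 1;
  auto gadd = [&](int i, double gx, double gy, double gz) {
    if (want_grad) { G[i] += gx; G[i + gn] += gy; G[i + 2 * gn] += gz; }
  };

  // bonds: E = k (r - r0)^2
  for (int m = 0; m < bi.size(); ++m) {
    int i = bi[m], j = bj[m];
    double dx = px(i) - px(j), dy = py(i) - py(j), dz = pz(i) - pz(j);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - br0[m];
    double e = bk[m] * dr * dr;
    e_bond += e;
    per[i] += 0.5 * e; per[j] += 0.5 * e;
    if (want_grad) {
      double f = 2.0 * bk[m] * dr / std::max(r, 1e-12);
      gadd(i, f * dx, f * dy, f * dz);
      gadd(j, -f * dx, -f * dy, -f * dz);
    }
  }

  // angles: E = k (theta - theta0)^2
  for (int m = 0; m < ai.size(); ++m) {
    int i = ai[m], j = aj[m], k = ak[m];
    double u[3] = {px(i) - px(j), py(i) - py(j), pz(i) - pz(j)};
    double v[3] = {px(k) - px(j), py(k) - py(j), pz(k) - pz(j)};
    double lu = std::sqrt(dot3(u, u)), lv = std::sqrt(dot3(v, v));
    double c = dot3(u, v) / (lu * lv);
    c = std::max(-1.0 + 1e-12, std::min(1.0 - 1e-12, c));
    double th = std::acos(c);
    double dth = th - at0[m];
    double e = akf[m] * dth * dth;
    e_angle += e;
    double third = e / 3.0;
    per[i] += third; per[j] += third; per[k] += third;
    if (want_grad) {
      double s = std::sqrt(1.0 - c * c);
      double dEdth = 2.0 * akf[m] * dth;
      double gi[3], gk[3];
      for (int d = 0; d < 3; ++d) {
        gi[d] = -(v[d] / (lu * lv) - c * u[d] / (lu * lu)) / s * dEdth;
        gk[d] = -(u[d] / (lu * lv) - c * v[d] / (lv * lv)) / s * dEdth;
      }
      gadd(i, gi[0], gi[1], gi[2]);
      gadd(k, gk[0], gk[1], gk[2]);
      gadd(j, -gi[0] - gk[0], -gi[1] - gk[1], -gi[2] - gk[2]);
    }
  }

  // torsions: E = (V/2) (1 + cos(n phi - gamma))
  for (int m = 0; m < ti.size(); ++m) {
    int i = ti[m], j = tj[m], k = tk[m], l = tl[m];
    double b1[3] = {px(j) - px(i), py(j) - py(i), pz(j) - pz(i)};
    double b2[3] = {px(k) - px(j), py(k) - py(j), pz(k) - pz(j)};
    double b3[3] = {px(l) - px(k), py(l) - py(k), pz(l) - pz(k)};
    double n1[3], n2[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    double ln1 = std::sqrt(dot3(n1, n1)), ln2 = std::sqrt(dot3(n2, n2));
    double lb2 = std::sqrt(dot3(b2, b2));
    if (ln1 < 1e-9 || ln2 < 1e-9 || lb2 < 1e-12) continue;  // degenerate
    double m1[3];
    cross3(n1, n2, m1);
    double x = dot3(n1, n2);
    double y = dot3(m1, b2) / lb2;
    double phi = std::atan2(y, x);
    double arg = tn[m] * phi - tg[m];
    double e = 0.5 * tv[m] * (1.0 + std::cos(arg));
    e_tors += e;
    double quarter = 0.25 * e;
    per[i] += quarter; per[j] += quarter; per[k] += quarter; per[l] += quarter;
    if (want_grad) {
      double dEdphi = -0.5 * tv[m] * tn[m] * std::sin(arg);
      double fi[3], fl[3];
      for (int d = 0; d < 3; ++d) {
        fi[d] = -lb2 / (ln1 * ln1) * n1[d];
        fl[d] = lb2 / (ln2 * ln2) * n2[d];
      }
      double t = dot3(b1, b2) / (lb2 * lb2);
      double u = dot3(b3, b2) / (lb2 * lb2);
      for (int d = 0; d < 3; ++d) {
        double gi = dEdphi * fi[d];
        double gl = dEdphi * fl[d];
        double gj = dEdphi * (-(1.0 + t) * fi[d] + u * fl[d]);
        double gk = dEdphi * (t * fi[d] - (1.0 + u) * fl[d]);
        if (d == 0) { gadd(i, gi, 0, 0); gadd(j, gj, 0, 0); gadd(k, gk, 0, 0); gadd(l, gl, 0, 0); }
        else if (d == 1) { gadd(i, 0, gi, 0); gadd(j, 0, gj, 0); gadd(k, 0, gk, 0); gadd(l, 0, gl, 0); }
        else { gadd(i, 0, 0, gi); gadd(j, 0, 0, gj); gadd(k, 0, 0, gk); gadd(l, 0, 0, gl); }
      }
    }
  }

  // nonbonded: 12-6 LJ (Lorentz-Berthelot) + optional Coulomb, truncated
  std::unordered_set<long long> excl;
  excl.reserve((exi.size() + p14i.size()) * 2 + 8);
  for (int m = 0; m < exi.size(); ++m)
    excl.insert((long long)exi[m] * n + exj[m]);
  for (int m = 0; m < p14i.size(); ++m)   // 1-4 handled separately
    excl.insert((long long)p14i[m] * n + p14j[m]);
  const double cut2 = cutoff * cutoff;
  const bool coul = q.size() == n && kcoul != 0.0;
  auto pair_e = [&](int i, int j, double scale) {
    double dx = px(i) - px(j), dy = py(i) - py(j), dz = pz(i) - pz(j);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= cut2 || r2 < 1e-12) return;
    double sij = 0.5 * (sig[i] + sig[j]);
    double eij = std::sqrt(eps[i] * eps[j]);
    double s2 = sij * sij / r2;
    double s6 = s2 * s2 * s2;
    double e = scale * 4.0 * eij * (s6 * s6 - s6);
    e_vdw += e;
    double f = scale * 24.0 * eij * (2.0 * s6 * s6 - s6) / r2; // -dE/dr / r
    double ec = 0, fc = 0;
    if (coul) {
      double r = std::sqrt(r2);
      ec = scale * kcoul * q[i] * q[j] / r;
      fc = ec / r2;
      e_coul += ec;
    }
    per[i] += 0.5 * (e + ec); per[j] += 0.5 * (e + ec);
    if (want_grad) {
      double ft = -(f + fc);     // gradient = dE/dx etc.
      gadd(i, ft * dx, ft * dy, ft * dz);
      gadd(j, -ft * dx, -ft * dy, -ft * dz);
    }
  };
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (excl.count((long long)i * n + j)) continue;
      pair_e(i, j, 1.0);
    }
  }
  for (int m = 0; m < p14i.size(); ++m)
    pair_e(p14i[m], p14j[m], scale14);

  double total = e_bond + e_angle + e_tors + e_vdw + e_coul;
  List out = List::create(_["total"] = total, _["bond"] = e_bond,
                          _["angle"] = e_angle, _["torsion"] = e_tors,
                          _["vdw"] = e_vdw, _["coulomb"] = e_coul,
                          _["per_atom"] = per);
  if (want_grad) out["gradient"] = grad;
  return out;
}
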