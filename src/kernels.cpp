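// Energy/gradient kernels for the hybrid protein-heme model.
//
// cpp_total evaluates every term of the Hamiltonian in one pass over a
// single coordinate matrix P (n x 3, nm) using precomputed index tables
// (1-based, prepared once per system in R), and returns the per-term
// energies (kJ/mol) together with the full gradient dE/dP.
// cpp_qw computes the Q_w structural-similarity metric and its gradient
// (needed for the umbrella bias force).
#include <Rcpp.h>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }
static inline double sech2(double x) { double t = std::tanh(x); return 1.0 - t * t; }

// dense row access on the raw column-major buffer
struct Coords {
  const double* p;
  int n;
  void row(int i, double* out) const {
    out[0] = p[i]; out[1] = p[i + n]; out[2] = p[i + 2 * n];
  }
};
struct Grad {
  double* g;
  int n;
  void add(int i, const double* v, double w) {
    g[i] += w * v[0]; g[i + n] += w * v[1]; g[i + 2 * n] += w * v[2];
  }
};

// radial pair helper: accumulates dEdr along the unit vector a -> b
static inline void radial(Grad& G, int i, int j, const double* d, double r,
                          double dEdr) {
  double u[3] = {d[0] / r, d[1] / r, d[2] / r};
  G.add(i, u, dEdr);
  G.add(j, u, -dEdr);
}

// ---- per-term workers ---------------------------------------------------

static double w_screened_coulomb(const Coords& P, Grad& G,
                                 const IntegerVector& ia, const IntegerVector& ib,
                                 const NumericVector& qq, double kappa) {
  double E = 0, a[3], b[3], d[3];
  for (int k = 0; k < ia.size(); ++k) {
    int i = ia[k] - 1, j = ib[k] - 1;
    P.row(i, a); P.row(j, b);
    for (int c = 0; c < 3; ++c) d[c] = a[c] - b[c];
    double r = norm3(d);
    if (r < 1e-12) stop("zero distance between charged sites");
    double ex = std::exp(-kappa * r);
    E += qq[k] / r * ex;
    radial(G, i, j, d, r, qq[k] * ex * (-1.0 / (r * r) - kappa / r));
  }
  return E;
}

static double w_gauss_pairs(const Coords& P, Grad& G,
                            const IntegerVector& ia, const IntegerVector& ib,
                            const NumericVector& lam, const NumericVector& r0,
                            double width) {
  double E = 0, a[3], b[3], d[3];
  for (int k = 0; k < ia.size(); ++k) {
    int i = ia[k] - 1, j = ib[k] - 1;
    P.row(i, a); P.row(j, b);
    for (int c = 0; c < 3; ++c) d[c] = a[c] - b[c];
    double r = norm3(d);
    if (r < 1e-12) continue;
    double dr = r - r0[k];
    double e = lam[k] * std::exp(-width * dr * dr);
    E += e;
    radial(G, i, j, d, r, -2.0 * width * dr * e);
  }
  return E;
}

static double w_burial(const Coords& P, Grad& G,
                       const IntegerVector& ia, const IntegerVector& ib,
                       double pref, double r0) {
  double E = 0, a[3], b[3], d[3];
  for (int k = 0; k < ia.size(); ++k) {
    int i = ia[k] - 1, j = ib[k] - 1;
    P.row(i, a); P.row(j, b);
    for (int c = 0; c < 3; ++c) d[c] = a[c] - b[c];
    double r = norm3(d);
    if (r < 1e-12) continue;
    double x = 8.0 * (r - r0);
    E += pref * (1.0 - std::tanh(x));
    radial(G, i, j, d, r, -8.0 * pref * sech2(x));
  }
  return E;
}

static double w_excl(const Coords& P, Grad& G,
                     const IntegerVector& ia, const IntegerVector& ib,
                     double lambda, double r0) {
  double E = 0, a[3], b[3], d[3];
  for (int k = 0; k < ia.size(); ++k) {
    int i = ia[k] - 1, j = ib[k] - 1;
    P.row(i, a); P.row(j, b);
    for (int c = 0; c < 3; ++c) d[c] = a[c] - b[c];
    double r = norm3(d);
    if (r >= r0 || r < 1e-12) continue;
    double dr = r - r0;
    E += lambda * dr * dr;
    radial(G, i, j, d, r, 2.0 * lambda * dr);
  }
  return E;
}

static double w_thioester(const Coords& P, Grad& G,
                          const IntegerVector& ia, const IntegerVector& ib,
                          double lambda, double r0) {
  double E = 0, a[3], b[3], d[3];
  for (int k = 0; k < ia.size(); ++k) {
    int i = ia[k] - 1, j = ib[k] - 1;
    P.row(i, a); P.row(j, b);
    for (int c = 0; c < 3; ++c) d[c] = a[c] - b[c];
    double r = norm3(d);
    if (r < 1e-12) continue;
    double dr = r - r0;
    double g = std::exp(-4.0 * dr * dr);
    double t3 = std::tanh(3.0 * dr), t32 = std::tanh(32.0 * dr);
    E += lambda * g * (1.0 - t3) * (1.0 + t32);
    double df = g * (-8.0 * dr * (1.0 - t3) * (1.0 + t32)
                     - 3.0 * (1.0 - t3 * t3) * (1.0 + t32)
                     + 32.0 * (1.0 - t3) * (1.0 - t32 * t32));
    radial(G, i, j, d, r, lambda * df);
  }
  return E;
}

// Fe coordinate-covalent restraint; face != 0 masks residues whose Cbeta
// lies on that side of the heme plane (occupied distal face)
static double w_fe_cc(const Coords& P, Grad& G,
                      const IntegerVector& icb, int ife,
                      const IntegerVector& in4, const NumericVector& lam,
                      double r0, double th0, double expSign, double face) {
  double E = 0;
  double fe[3], cb[3], u[3], uh[3];
  double nv[4][3], vh[4][3], dlen[4];
  double s0 = std::sin(th0);
  P.row(ife - 1, fe);
  for (int j = 0; j < 4; ++j) {
    P.row(in4[j] - 1, nv[j]);
    for (int c = 0; c < 3; ++c) nv[j][c] -= fe[c];
    dlen[j] = norm3(nv[j]);
    if (dlen[j] < 1e-12) stop("pyrrole N coincides with Fe");
    for (int c = 0; c < 3; ++c) vh[j][c] = nv[j][c] / dlen[j];
  }
  double nrm[3] = {0, 0, 0};
  if (face != 0) {
    double e1[3], e2[3];
    for (int c = 0; c < 3; ++c) { e1[c] = nv[0][c] - nv[2][c]; e2[c] = nv[1][c] - nv[3][c]; }
    cross3(e1, e2, nrm);
  }
  for (int k = 0; k < icb.size(); ++k) {
    if (lam[k] == 0.0) continue;
    P.row(icb[k] - 1, cb);
    for (int c = 0; c < 3; ++c) u[c] = cb[c] - fe[c];
    double r = norm3(u);
    if (r < 1e-12) continue;
    if (face != 0) {
      double side = dot3(u, nrm);
      if ((side > 0 && face > 0) || (side < 0 && face < 0)) continue;
    }
    for (int c = 0; c < 3; ++c) uh[c] = u[c] / r;
    double dr = r - r0;
    double Gfac = std::exp(expSign * dr * dr);
    double dGdr = expSign * 2.0 * dr * Gfac;
    double g[4], dgds[4], cj[4], sj[4], P4 = 1.0;
    for (int j = 0; j < 4; ++j) {
      double c = std::max(-1.0, std::min(1.0, dot3(uh, vh[j])));
      double s = std::sqrt(std::max(1.0 - c * c, 1e-12));
      double x = 2.0 * (s - s0);
      double t = std::tanh(x);
      g[j] = (1.0 + t) / 2.0;
      dgds[j] = 1.0 - t * t;
      cj[j] = c; sj[j] = s;
      P4 *= g[j];
    }
    E += lam[k] * Gfac * P4;
    double wr = lam[k] * dGdr * P4;
    G.add(icb[k] - 1, uh, wr);
    G.add(ife - 1, uh, -wr);
    for (int j = 0; j < 4; ++j) {
      if (g[j] < 1e-14) continue;
      double coef = lam[k] * Gfac * (P4 / g[j]) * dgds[j] * (-cj[j] / sj[j]);
      double dcb[3], dnj[3], dfe[3];
      for (int c = 0; c < 3; ++c) {
        dcb[c] = (vh[j][c] - cj[j] * uh[c]) / r;
        dnj[c] = (uh[c] - cj[j] * vh[j][c]) / dlen[j];
        dfe[c] = -dcb[c] - dnj[c];
      }
      G.add(icb[k] - 1, dcb, coef);
      G.add(in4[j] - 1, dnj, coef);
      G.add(ife - 1, dfe, coef);
    }
  }
  return E;
}

// Backbone N-H ... carboxylate-O hydrogen bond.  The virtual sites
//   H_i = ch . (Ca_{i-1}, Ca_i, O_{i-1}),  N_i = cn . (same)
// are built here and their gradients chain-ruled onto the parent beads.
static double w_hb_backbone(const Coords& P, Grad& G,
                            const IntegerVector& ica_prev,
                            const IntegerVector& ica,
                            const IntegerVector& io_prev,
                            const IntegerVector& iox,
                            const NumericVector& cn, const NumericVector& ch,
                            double lambda, double r0, double th0) {
  double E = 0;
  double ap[3], ai[3], op[3], h[3], nn[3], o[3], u[3], uh[3], w[3], wh[3], vhat[3];
  for (int k = 0; k < ica.size(); ++k) {
    int rp = ica_prev[k] - 1, ri = ica[k] - 1, ro = io_prev[k] - 1;
    P.row(rp, ap); P.row(ri, ai); P.row(ro, op);
    for (int c = 0; c < 3; ++c) {
      h[c] = ch[0] * ap[c] + ch[1] * ai[c] + ch[2] * op[c];
      nn[c] = cn[0] * ap[c] + cn[1] * ai[c] + cn[2] * op[c];
      u[c] = nn[c] - h[c];
    }
    double ru = norm3(u);
    if (ru < 1e-12) continue;
    for (int c = 0; c < 3; ++c) uh[c] = u[c] / ru;
    for (int jj = 0; jj < iox.size(); ++jj) {
      int j = iox[jj] - 1;
      P.row(j, o);
      for (int c = 0; c < 3; ++c) w[c] = h[c] - o[c];
      double r = norm3(w);
      if (r < 1e-12) continue;
      for (int c = 0; c < 3; ++c) { wh[c] = w[c] / r; vhat[c] = -w[c] / r; }
      double dr = r - r0;
      double gau = std::exp(-4.0 * dr * dr);
      double cth = std::max(-1.0, std::min(1.0, dot3(uh, vhat)));
      double sth = std::sqrt(std::max(1.0 - cth * cth, 1e-12));
      double th = std::acos(cth);
      double x = 4.0 * (th - th0) - 6.0;
      double gate = (std::tanh(x) + 1.0) / 2.0;
      E += lambda * gau * gate;
      double gH[3] = {0, 0, 0}, gN[3] = {0, 0, 0}, gO[3] = {0, 0, 0};
      // radial part acts on H and O
      double wr = lambda * (-8.0 * dr * gau) * gate;
      for (int c = 0; c < 3; ++c) { gH[c] += wr * wh[c]; gO[c] -= wr * wh[c]; }
      // angular part: dth/dc = -1/s, dgate/dth = 2 sech^2
      double coef = lambda * gau * 2.0 * sech2(x) * (-1.0 / sth);
      for (int c = 0; c < 3; ++c) {
        double dN = (vhat[c] - cth * uh[c]) / ru;
        double dO = (uh[c] - cth * vhat[c]) / r;
        gN[c] += coef * dN;
        gO[c] += coef * dO;
        gH[c] += coef * (-dN - dO);
      }
      // chain rule the virtual sites onto parent beads
      for (int c = 0; c < 3; ++c) {
        double vH = gH[c], vN = gN[c];
        G.g[rp + c * G.n] += ch[0] * vH + cn[0] * vN;
        G.g[ri + c * G.n] += ch[1] * vH + cn[1] * vN;
        G.g[ro + c * G.n] += ch[2] * vH + cn[2] * vN;
        G.g[j + c * G.n] += gO[c];
      }
    }
  }
  return E;
}

static double w_bonds(const Coords& P, Grad& G,
                      const IntegerVector& ia, const IntegerVector& ib,
                      const NumericVector& k, const NumericVector& r0) {
  double E = 0, a[3], b[3], d[3];
  for (int t = 0; t < ia.size(); ++t) {
    int i = ia[t] - 1, j = ib[t] - 1;
    P.row(i, a); P.row(j, b);
    for (int c = 0; c < 3; ++c) d[c] = a[c] - b[c];
    double r = norm3(d);
    if (r < 1e-12) continue;
    double dr = r - r0[t];
    E += k[t] * dr * dr;
    radial(G, i, j, d, r, 2.0 * k[t] * dr);
  }
  return E;
}

static double w_angles(const Coords& P, Grad& G,
                       const IntegerVector& ia, const IntegerVector& ib,
                       const IntegerVector& ic, const NumericVector& k,
                       const NumericVector& th0) {
  double E = 0, a[3], b[3], cc[3], u[3], v[3], uh[3], vh[3];
  for (int t = 0; t < ia.size(); ++t) {
    int i = ia[t] - 1, j = ib[t] - 1, l = ic[t] - 1;
    P.row(i, a); P.row(j, b); P.row(l, cc);
    for (int c = 0; c < 3; ++c) { u[c] = a[c] - b[c]; v[c] = cc[c] - b[c]; }
    double ru = norm3(u), rv = norm3(v);
    if (ru < 1e-12 || rv < 1e-12) continue;
    for (int c = 0; c < 3; ++c) { uh[c] = u[c] / ru; vh[c] = v[c] / rv; }
    double cth = std::max(-1.0, std::min(1.0, dot3(uh, vh)));
    // the apparent 1/sin singularity cancels against |v - c u| = sin(theta);
    // only the exactly collinear direction is undefined
    double sth = std::max(std::sqrt(std::max(1.0 - cth * cth, 0.0)), 1e-8);
    double dth = std::acos(cth) - th0[t];
    E += k[t] * dth * dth;
    double coef = 2.0 * k[t] * dth * (-1.0 / sth);
    for (int c = 0; c < 3; ++c) {
      double da = (vh[c] - cth * uh[c]) / ru;
      double dc = (uh[c] - cth * vh[c]) / rv;
      G.g[i + c * G.n] += coef * da;
      G.g[l + c * G.n] += coef * dc;
      G.g[j + c * G.n] += coef * (-da - dc);
    }
  }
  return E;
}

static double w_dihedrals(const Coords& P, Grad& G,
                          const IntegerVector& ia, const IntegerVector& ib,
                          const IntegerVector& ic, const IntegerVector& id,
                          const NumericVector& k, const NumericVector& nper,
                          const NumericVector& delta) {
  double E = 0;
  double p1[3], p2[3], p3[3], p4[3], b1[3], b2[3], b3[3], n1[3], n2[3], cx[3];
  for (int t = 0; t < ia.size(); ++t) {
    int i = ia[t] - 1, j = ib[t] - 1, l = ic[t] - 1, q = id[t] - 1;
    P.row(i, p1); P.row(j, p2); P.row(l, p3); P.row(q, p4);
    for (int c = 0; c < 3; ++c) {
      b1[c] = p2[c] - p1[c]; b2[c] = p3[c] - p2[c]; b3[c] = p4[c] - p3[c];
    }
    cross3(b1, b2, n1); cross3(b2, b3, n2);
    double ln1 = dot3(n1, n1), ln2 = dot3(n2, n2), lb2 = norm3(b2);
    if (ln1 < 1e-18 || ln2 < 1e-18 || lb2 < 1e-12) continue;
    cross3(n1, n2, cx);
    double phi = std::atan2(dot3(cx, b2) / lb2, dot3(n1, n2));
    double arg = nper[t] * phi - delta[t];
    E += k[t] * (1.0 + std::cos(arg));
    double dEdphi = -k[t] * nper[t] * std::sin(arg);
    double c12 = dot3(b1, b2) / (lb2 * lb2), c32 = dot3(b3, b2) / (lb2 * lb2);
    for (int c = 0; c < 3; ++c) {
      double d1 = -lb2 / ln1 * n1[c];
      double d4 = lb2 / ln2 * n2[c];
      double d2 = (-1.0 - c12) * d1 + c32 * d4;
      double d3 = c12 * d1 + (-1.0 - c32) * d4;
      G.g[i + c * G.n] += dEdphi * d1;
      G.g[j + c * G.n] += dEdphi * d2;
      G.g[l + c * G.n] += dEdphi * d3;
      G.g[q + c * G.n] += dEdphi * d4;
    }
  }
  return E;
}

static double w_lj(const Coords& P, Grad& G,
                   const IntegerVector& ia, const IntegerVector& ib,
                   const NumericVector& sig, const NumericVector& eps,
                   const NumericVector& scale) {
  double E = 0, a[3], b[3], d[3];
  for (int t = 0; t < ia.size(); ++t) {
    int i = ia[t] - 1, j = ib[t] - 1;
    P.row(i, a); P.row(j, b);
    for (int c = 0; c < 3; ++c) d[c] = a[c] - b[c];
    double r = norm3(d);
    if (r < 1e-12) stop("zero distance in LJ pair");
    // soft-core cap: below 0.8 sigma the potential continues linearly so
    // rare thermal core breaches cannot destabilize the integrator
    double rc = 0.8 * sig[t];
    double re = std::max(r, rc);
    double sr = sig[t] / re;
    double sr6 = sr * sr * sr; sr6 = sr6 * sr6;
    double sr12 = sr6 * sr6;
    double Ee = 4.0 * eps[t] * (sr12 - sr6);
    double dEdr = 4.0 * eps[t] * (-12.0 * sr12 + 6.0 * sr6) / re;
    if (r < rc) Ee += dEdr * (r - rc);
    E += scale[t] * Ee;
    radial(G, i, j, d, r, scale[t] * dEdr);
  }
  return E;
}

static double w_gauss_wells(const Coords& P, Grad& G,
                            const IntegerVector& ia, const IntegerVector& ib,
                            const NumericVector& eps, const NumericVector& r0,
                            const NumericVector& sigma) {
  double E = 0, a[3], b[3], d[3];
  for (int t = 0; t < ia.size(); ++t) {
    int i = ia[t] - 1, j = ib[t] - 1;
    P.row(i, a); P.row(j, b);
    for (int c = 0; c < 3; ++c) d[c] = a[c] - b[c];
    double r = norm3(d);
    if (r < 1e-12) continue;
    double dr = r - r0[t];
    double e = -eps[t] * std::exp(-dr * dr / (2.0 * sigma[t] * sigma[t]));
    E += e;
    radial(G, i, j, d, r, e * (-dr / (sigma[t] * sigma[t])));
  }
  return E;
}

static double w_chirality(const Coords& P, Grad& G,
                          const IntegerVector& ia, const IntegerVector& ib,
                          const IntegerVector& ic, const IntegerVector& id,
                          const NumericVector& k, const NumericVector& d0) {
  double E = 0;
  double pa[3], pb[3], pc[3], pd[3], v1[3], v2[3], w[3], c1[3], c2[3], c3[3];
  for (int t = 0; t < ia.size(); ++t) {
    int i = ia[t] - 1, j = ib[t] - 1, l = ic[t] - 1, q = id[t] - 1;
    P.row(i, pa); P.row(j, pb); P.row(l, pc); P.row(q, pd);
    for (int c = 0; c < 3; ++c) {
      v1[c] = pb[c] - pa[c]; v2[c] = pc[c] - pb[c]; w[c] = pd[c] - pb[c];
    }
    cross3(v1, v2, c1);
    double dd = dot3(c1, w) - d0[t];
    E += k[t] * dd * dd;
    double coef = 2.0 * k[t] * dd;
    cross3(v2, w, c2);
    cross3(w, v1, c3);
    for (int c = 0; c < 3; ++c) {
      G.g[i + c * G.n] += coef * (-c2[c]);
      G.g[j + c * G.n] += coef * (c2[c] - c3[c] - c1[c]);
      G.g[l + c * G.n] += coef * c3[c];
      G.g[q + c * G.n] += coef * c1[c];
    }
  }
  return E;
}

static double w_confine(const Coords& P, Grad& G, const NumericVector& center,
                        double radius, double k) {
  double E = 0, a[3], d[3];
  for (int i = 0; i < P.n; ++i) {
    P.row(i, a);
    for (int c = 0; c < 3; ++c) d[c] = a[c] - center[c];
    double r = norm3(d);
    if (r <= radius || r < 1e-12) continue;
    double dr = r - radius;
    E += k * dr * dr;
    double u[3] = {d[0] / r, d[1] / r, d[2] / r};
    G.add(i, u, 2.0 * k * dr);
  }
  return E;
}

// ---- main entry ---------------------------------------------------------

static inline IntegerVector iv(const List& l, const char* nm) {
  return as<IntegerVector>(l[nm]);
}
static inline NumericVector nv(const List& l, const char* nm) {
  return as<NumericVector>(l[nm]);
}
static inline double dv(const List& l, const char* nm) {
  return as<double>(l[nm]);
}

// Evaluate all terms listed in `tab` on coordinates P.
// [[Rcpp::export]]
List cpp_total(NumericMatrix P, List tab) {
  int n = P.nrow();
  NumericMatrix Gm(n, 3);
  Coords C{REAL(P), n};
  Grad G{REAL(Gm), n};
  double fe_cc = 0, elec = 0, hb_bb = 0, hb_sc = 0, burial = 0, excl = 0,
         thio = 0, heme_int = 0, standin = 0, restraint = 0;

  if (tab.containsElementNamed("fe_cc")) {
    List t = tab["fe_cc"];
    fe_cc = w_fe_cc(C, G, iv(t, "icb"), as<int>(t["ife"]), iv(t, "in4"),
                    nv(t, "lam"), dv(t, "r0"), dv(t, "th0"), dv(t, "sign"),
                    dv(t, "face"));
  }
  if (tab.containsElementNamed("elec")) {
    List t = tab["elec"];
    elec = w_screened_coulomb(C, G, iv(t, "ia"), iv(t, "ib"), nv(t, "qq"),
                              dv(t, "kappa"));
  }
  if (tab.containsElementNamed("hb_bb")) {
    List t = tab["hb_bb"];
    hb_bb = w_hb_backbone(C, G, iv(t, "ica_prev"), iv(t, "ica"),
                          iv(t, "io_prev"), iv(t, "iox"), nv(t, "cn"),
                          nv(t, "ch"), dv(t, "lambda"), dv(t, "r0"),
                          dv(t, "th0"));
  }
  if (tab.containsElementNamed("hb_sc")) {
    List t = tab["hb_sc"];
    hb_sc = w_gauss_pairs(C, G, iv(t, "ia"), iv(t, "ib"), nv(t, "lam"),
                          nv(t, "r0"), 4.0);
  }
  if (tab.containsElementNamed("burial")) {
    List t = tab["burial"];
    burial = w_burial(C, G, iv(t, "ia"), iv(t, "ib"), dv(t, "pref"),
                      dv(t, "r0"));
  }
  if (tab.containsElementNamed("excl")) {
    List t = tab["excl"];
    excl = w_excl(C, G, iv(t, "ia"), iv(t, "ib"), dv(t, "lambda"),
                  dv(t, "r0"));
  }
  if (tab.containsElementNamed("thio")) {
    List t = tab["thio"];
    thio = w_thioester(C, G, iv(t, "ia"), iv(t, "ib"), dv(t, "lambda"),
                       dv(t, "r0"));
  }
  if (tab.containsElementNamed("heme_int")) {
    List t = tab["heme_int"];
    List b = t["bonds"], a = t["angles"], d = t["dihedrals"], lj = t["lj"],
         cl = t["coul"];
    heme_int += w_bonds(C, G, iv(b, "ia"), iv(b, "ib"), nv(b, "k"), nv(b, "r0"));
    heme_int += w_angles(C, G, iv(a, "ia"), iv(a, "ib"), iv(a, "ic"),
                         nv(a, "k"), nv(a, "th0"));
    heme_int += w_dihedrals(C, G, iv(d, "ia"), iv(d, "ib"), iv(d, "ic"),
                            iv(d, "id"), nv(d, "k"), nv(d, "n"),
                            nv(d, "delta"));
    heme_int += w_lj(C, G, iv(lj, "ia"), iv(lj, "ib"), nv(lj, "sig"),
                     nv(lj, "eps"), nv(lj, "scale"));
    if (iv(cl, "ia").size())
      heme_int += w_screened_coulomb(C, G, iv(cl, "ia"), iv(cl, "ib"),
                                     nv(cl, "qq"), dv(cl, "kappa"));
  }
  if (tab.containsElementNamed("standin")) {
    List t = tab["standin"];
    List wl = t["wells"], bd = t["bonds"], ch = t["chir"];
    standin += w_gauss_wells(C, G, iv(wl, "ia"), iv(wl, "ib"), nv(wl, "eps"),
                             nv(wl, "r0"), nv(wl, "sigma"));
    standin += w_bonds(C, G, iv(bd, "ia"), iv(bd, "ib"), nv(bd, "k"),
                       nv(bd, "r0"));
    if (iv(ch, "ia").size())
      standin += w_chirality(C, G, iv(ch, "ia"), iv(ch, "ib"), iv(ch, "ic"),
                             iv(ch, "id"), nv(ch, "k"), nv(ch, "d0"));
    if (t.containsElementNamed("angles")) {
      List an = t["angles"];
      if (iv(an, "ia").size())
        standin += w_angles(C, G, iv(an, "ia"), iv(an, "ib"), iv(an, "ic"),
                            nv(an, "k"), nv(an, "th0"));
    }
    if (t.containsElementNamed("dihedrals")) {
      List dh = t["dihedrals"];
      if (iv(dh, "ia").size())
        standin += w_dihedrals(C, G, iv(dh, "ia"), iv(dh, "ib"), iv(dh, "ic"),
                               iv(dh, "id"), nv(dh, "k"), nv(dh, "n"),
                               nv(dh, "delta"));
    }
    if (t.containsElementNamed("excl")) {
      List ex = t["excl"];
      if (iv(ex, "ia").size())
        standin += w_excl(C, G, iv(ex, "ia"), iv(ex, "ib"), dv(ex, "lambda"),
                          dv(ex, "r0"));
    }
  }
  if (tab.containsElementNamed("confine")) {
    List t = tab["confine"];
    restraint = w_confine(C, G, nv(t, "center"), dv(t, "radius"), dv(t, "k"));
  }
  NumericVector terms = NumericVector::create(
    _["fe_cc"] = fe_cc, _["elec"] = elec, _["hb_backbone"] = hb_bb,
    _["hb_sidechain"] = hb_sc, _["burial"] = burial, _["excl"] = excl,
    _["thioester"] = thio, _["heme_internal"] = heme_int,
    _["protein_standin"] = standin, _["restraint"] = restraint);
  return List::create(_["terms"] = terms, _["grad"] = Gm);
}

// Q_w and its gradient over the listed Calpha pair rows of P.
//   q = pref * sum exp(-(r - rn)^2 / (2 sigma^2))
// [[Rcpp::export]]
List cpp_qw(NumericMatrix P, IntegerVector ia, IntegerVector ib,
            NumericVector rn, NumericVector sigma, double pref) {
  int m = ia.size(), n = P.nrow();
  NumericMatrix Gm(n, 3);
  Coords C{REAL(P), n};
  Grad G{REAL(Gm), n};
  double q = 0, a[3], b[3], d[3];
  for (int t = 0; t < m; ++t) {
    int i = ia[t] - 1, j = ib[t] - 1;
    C.row(i, a); C.row(j, b);
    for (int c = 0; c < 3; ++c) d[c] = a[c] - b[c];
    double r = norm3(d);
    if (r < 1e-12) continue;
    double dr = r - rn[t];
    double s2 = sigma[t] * sigma[t];
    double e = pref * std::exp(-dr * dr / (2.0 * s2));
    q += e;
    radial(G, i, j, d, r, e * (-dr / s2));
  }
  return List::create(_["q"] = q, _["grad"] = Gm);
}
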