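// Core finite-element kernels for quasi-static left-ventricular mechanics:
// Holzapfel-Ogden passive law (isochoric/volumetric split), time-varying
// active fiber tension with length-dependent calcium sensitivity, total-
// Lagrangian 8-node hexahedra with selective reduced integration of the
// volumetric penalty, follower pressure loads on the endocardium, and
// triangulated cavity-volume tracking with analytic gradients.
//
// Units: lengths cm, stresses MPa, volumes ml (= cm^3), time s.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// ---------------------------------------------------------------------------
// parameter structs

struct MatP {
  double a, b, af, bf, as, bs, afs, bfs, D;
};
struct ActP {
  double ca0, ca0max, B, l0, lR, m, b, t0;
};

static MatP matp_from_list(const List& l) {
  MatP m;
  m.a = l["a"]; m.b = l["b"]; m.af = l["a_f"]; m.bf = l["b_f"];
  m.as = l["a_s"]; m.bs = l["b_s"]; m.afs = l["a_fs"]; m.bfs = l["b_fs"];
  m.D = l["Dpar"];
  return m;
}
static ActP actp_from_list(const List& l) {
  ActP a;
  a.ca0 = l["ca0"]; a.ca0max = l["ca0_max"]; a.B = l["b_len"];
  a.l0 = l["l0"]; a.lR = l["lR"]; a.m = l["m_relax"]; a.b = l["b_relax"];
  a.t0 = l["t0"];
  return a;
}

// ---------------------------------------------------------------------------
// Voigt helpers: order [11, 22, 33, 12, 13, 23]; the 6x6 tangent D is laid out
// so that dS_v = D * dE_v with engineering shear strains (gamma = 2 E_offdiag).

static inline vec::fixed<6> voigt(const mat33& A) {
  vec::fixed<6> v;
  v(0) = A(0,0); v(1) = A(1,1); v(2) = A(2,2);
  v(3) = A(0,1); v(4) = A(0,2); v(5) = A(1,2);
  return v;
}

static inline void add_dyad(mat66& D, const vec::fixed<6>& a,
                            const vec::fixed<6>& b, double w) {
  if (w == 0.0) return;
  D += w * (a * b.t());
}

// (A (.) A)_{IJKL} = 0.5 (A_IK A_JL + A_IL A_JK) in the Voigt layout above
static mat66 codot(const mat33& A) {
  static const int idx[6][2] = {{0,0},{1,1},{2,2},{0,1},{0,2},{1,2}};
  mat66 D;
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 6; ++c) {
      int I = idx[r][0], J = idx[r][1], K = idx[c][0], L = idx[c][1];
      D(r,c) = 0.5 * (A(I,K)*A(J,L) + A(I,L)*A(J,K));
    }
  return D;
}

// ---------------------------------------------------------------------------
// active tension law

static double active_T0_scalar(double t, double Eff, double tmax, const ActP& a) {
  if (tmax <= 0.0 || t <= 0.0) return 0.0;
  double arg = 2.0 * Eff + 1.0;
  if (arg <= 0.0) return 0.0;
  double l = a.lR * std::sqrt(arg);
  if (l <= a.l0) return 0.0;
  double den = std::expm1(a.B * (l - a.l0));
  if (den <= 0.0) return 0.0;
  double eca50 = a.ca0max / std::sqrt(den);
  double tr = a.m * l + a.b;
  if (tr < 1e-6) tr = 1e-6;
  double w;
  if (t <= a.t0) w = M_PI * t / a.t0;
  else if (t <= a.t0 + tr) w = M_PI * (t - a.t0 + tr) / tr;
  else return 0.0;
  double Ct = 0.5 * (1.0 - std::cos(w));
  double c2 = a.ca0 * a.ca0;
  return tmax * c2 / (c2 + eca50 * eca50) * Ct;
}

// [[Rcpp::export(name = ".active_T0_cpp")]]
double active_T0_cpp(double t, double Eff, double tmax, List actpar) {
  ActP a = actp_from_list(actpar);
  return active_T0_scalar(t, Eff, tmax, a);
}

// ---------------------------------------------------------------------------
// material point: stress, tangent, energy.
// include_dev: isochoric HO terms + active fiber stress
// include_vol: volumetric penalty
// Returns false on non-finite / inverted states (caller cuts the step back).

static bool ho_point(const mat33& F, const vec3& f0, const vec3& s0,
                     const MatP& mp, double tmax, const ActP& ap, double time,
                     bool include_dev, bool include_vol, bool want_tangent,
                     mat33& S, mat66& Dm, double& psi) {
  double J = det(F);
  if (!std::isfinite(J) || J <= 1e-8) return false;
  mat33 C = F.t() * F;
  mat33 Ci;
  if (!inv_sympd(Ci, symmatu(C))) {
    if (!inv(Ci, C)) return false;
  }
  S.zeros(); Dm.zeros(); psi = 0.0;

  const vec::fixed<6> vCi = voigt(Ci);

  if (include_dev) {
    double Jm23 = std::pow(J, -2.0/3.0);
    mat33 Cb = Jm23 * C;
    double I1b = trace(Cb);
    double I4fb = as_scalar(f0.t() * Cb * f0);
    double I4sb = as_scalar(s0.t() * Cb * s0);
    double I8b  = as_scalar(f0.t() * Cb * s0);

    double e1 = mp.b * (I1b - 3.0);
    double q4f = I4fb - 1.0, q4s = I4sb - 1.0;
    double e4f = mp.bf * q4f * q4f, e4s = mp.bs * q4s * q4s;
    double e8  = mp.bfs * I8b * I8b;
    if (e1 > 60.0 || e4f > 60.0 || e4s > 60.0 || e8 > 60.0) return false;

    double ex1 = std::exp(e1), ex4f = std::exp(e4f), ex4s = std::exp(e4s),
           ex8 = std::exp(e8);

    // first derivatives wrt the isochoric invariants
    double g1 = 0.5 * mp.a * ex1;
    double g4f = (q4f > 0.0) ? mp.af * q4f * ex4f : 0.0;   // tension-only
    double g4s = (q4s > 0.0) ? mp.as * q4s * ex4s : 0.0;
    double g8  = mp.afs * I8b * ex8;

    mat33 ff = f0 * f0.t();
    mat33 ss = s0 * s0.t();
    mat33 fs = 0.5 * (f0 * s0.t() + s0 * f0.t());
    mat33 I3x(fill::eye);

    mat33 Shat = 2.0 * (g1 * I3x + g4f * ff + g4s * ss + g8 * fs);
    double trSC = accu(Shat % C);
    mat33 Siso = Jm23 * (Shat - (trSC / 3.0) * Ci);
    S += Siso;

    // energy (zero in the reference configuration)
    double pd = (mp.b > 1e-12) ? mp.a / (2.0*mp.b) * std::expm1(e1)
                               : 0.5 * mp.a * (I1b - 3.0);
    if (q4f > 0.0) pd += (mp.bf > 1e-12) ? mp.af/(2.0*mp.bf) * std::expm1(e4f)
                                         : 0.5 * mp.af * q4f * q4f;
    if (q4s > 0.0) pd += (mp.bs > 1e-12) ? mp.as/(2.0*mp.bs) * std::expm1(e4s)
                                         : 0.5 * mp.as * q4s * q4s;
    pd += (mp.bfs > 1e-12) ? mp.afs/(2.0*mp.bfs) * std::expm1(e8)
                           : 0.5 * mp.afs * I8b * I8b;
    psi += pd;

    if (want_tangent) {
      double h1 = 0.5 * mp.a * mp.b * ex1;
      double h4f = (q4f > 0.0) ? mp.af * (1.0 + 2.0*mp.bf*q4f*q4f) * ex4f : 0.0;
      double h4s = (q4s > 0.0) ? mp.as * (1.0 + 2.0*mp.bs*q4s*q4s) * ex4s : 0.0;
      double h8  = mp.afs * (1.0 + 2.0*mp.bfs*I8b*I8b) * ex8;
      double Jm43 = Jm23 * Jm23;

      auto addterm = [&](double alpha, const mat33& A) {
        if (alpha == 0.0) return;
        mat33 Ad = A - (accu(A % C) / 3.0) * Ci;   // projection P : A
        add_dyad(Dm, voigt(Ad), voigt(Ad), alpha * Jm43);
      };
      addterm(4.0 * h1, I3x);
      addterm(4.0 * h4f, ff);
      addterm(4.0 * h4s, ss);
      addterm(4.0 * h8, fs);

      Dm += (2.0/3.0) * Jm23 * trSC * codot(Ci);
      add_dyad(Dm, vCi, vCi, -(2.0/9.0) * Jm23 * trSC);
      const vec::fixed<6> vSiso = voigt(Siso);
      add_dyad(Dm, vCi, vSiso, -2.0/3.0);
      add_dyad(Dm, vSiso, vCi, -2.0/3.0);
    }

    // active fiber stress, referred to the reference configuration
    if (tmax > 0.0 && time > 0.0) {
      double I4f = as_scalar(f0.t() * C * f0);
      double Eff = 0.5 * (I4f - 1.0);
      double T0 = active_T0_scalar(time, Eff, tmax, ap);
      S += (T0 / I4f) * ff;
      if (want_tangent) {
        double h = 1e-6;
        double dT0 = (active_T0_scalar(time, Eff + h, tmax, ap)
                      - active_T0_scalar(time, Eff - h, tmax, ap)) / (2.0*h);
        double dtau = 0.5 * dT0 / I4f - T0 / (I4f * I4f);
        add_dyad(Dm, voigt(ff), voigt(ff), 2.0 * dtau);
      }
    }
  }

  if (include_vol) {
    double p = (J - 1.0/J) / mp.D;
    S += p * J * Ci;
    psi += ((J*J - 1.0)/2.0 - std::log(J)) / mp.D;
    if (want_tangent) {
      double dpdJ = (1.0 + 1.0/(J*J)) / mp.D;
      add_dyad(Dm, vCi, vCi, (p + J*dpdJ) * J);
      Dm += codot(Ci) * (-2.0 * J * p);
    }
  }
  return S.is_finite();
}

// exported material-point interface -----------------------------------------

// [[Rcpp::export(name = ".ho_point_cpp")]]
List ho_point_cpp(NumericMatrix Fm, NumericVector f0v, NumericVector s0v,
                  List matpar, double tmax, List actpar, double time) {
  mat33 F(Fm.begin());  // column-major, F is 3x3
  vec3 f0(f0v.begin()), s0(s0v.begin());
  MatP mp = matp_from_list(matpar);
  ActP ap = actp_from_list(actpar);
  mat33 S; mat66 D; double psi;
  bool ok = ho_point(F, f0, s0, mp, tmax, ap, time, true, true, true, S, D, psi);
  return List::create(_["ok"] = ok,
                      _["S"] = wrap(S),
                      _["Dm"] = wrap(D),
                      _["psi"] = psi);
}

// ---------------------------------------------------------------------------
// 8-node hexahedron shape functions (VTK node ordering: bottom quad CCW, then
// top quad), natural coordinates in [-1, 1]^3

static void hex_shape(double xi, double eta, double ze,
                      vec::fixed<8>& N, mat::fixed<8,3>& dN) {
  const double sx[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
  const double sy[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  const double sz[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  for (int a = 0; a < 8; ++a) {
    double px = 1.0 + sx[a]*xi, py = 1.0 + sy[a]*eta, pz = 1.0 + sz[a]*ze;
    N(a) = 0.125 * px * py * pz;
    dN(a,0) = 0.125 * sx[a] * py * pz;
    dN(a,1) = 0.125 * px * sy[a] * pz;
    dN(a,2) = 0.125 * px * py * sz[a];
  }
}

// min reference Jacobian per element (mesh quality)
// [[Rcpp::export(name = ".hex_min_jac_cpp")]]
NumericVector hex_min_jac_cpp(NumericMatrix Xm, IntegerMatrix conn) {
  int ne = conn.nrow();
  mat X(Xm.begin(), Xm.nrow(), 3);
  NumericVector out(ne);
  const double g = 1.0 / std::sqrt(3.0);
  vec::fixed<8> N; mat::fixed<8,3> dN;
  for (int e = 0; e < ne; ++e) {
    mat::fixed<3,8> Xe;
    for (int a = 0; a < 8; ++a)
      Xe.col(a) = X.row(conn(e,a) - 1).t();
    double mj = datum::inf;
    for (int q = 0; q < 8; ++q) {
      double xi = (q & 1) ? g : -g;
      double eta = (q & 2) ? g : -g;
      double ze = (q & 4) ? g : -g;
      hex_shape(xi, eta, ze, N, dN);
      mat33 J0 = Xe * dN;
      mj = std::min(mj, det(J0));
    }
    out[e] = mj;
  }
  return out;
}

// ---------------------------------------------------------------------------
// assembly: internal force, consistent tangent (values in a fixed canonical
// element-major order matching .lv_pattern_cpp), total strain energy.

// [[Rcpp::export(name = ".lv_pattern_cpp")]]
List lv_pattern_cpp(IntegerMatrix conn, int nnode) {
  int ne = conn.nrow();
  IntegerVector ti(ne * 576), tj(ne * 576);
  int k = 0;
  for (int e = 0; e < ne; ++e) {
    int dofs[24];
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        dofs[3*a + i] = 3 * (conn(e,a) - 1) + i + 1;  // 1-based dof
    for (int c = 0; c < 24; ++c)
      for (int r = 0; r < 24; ++r) {
        ti[k] = dofs[r];
        tj[k] = dofs[c];
        ++k;
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["ndof"] = 3 * nnode);
}

// [[Rcpp::export(name = ".lv_assemble_cpp")]]
List lv_assemble_cpp(NumericMatrix Xm, IntegerMatrix conn,
                     NumericMatrix f0m, NumericMatrix s0m,
                     NumericVector uv, List matpar, NumericVector tmax_el,
                     List actpar, double time, bool want_tangent) {
  int ne = conn.nrow();
  int nn = Xm.nrow();
  mat X(Xm.begin(), nn, 3);
  MatP mp = matp_from_list(matpar);
  ActP ap = actp_from_list(actpar);

  NumericVector fint(3 * nn);
  NumericVector Kv(want_tangent ? ne * 576 : 0);
  double psi_tot = 0.0;
  bool ok = true;

  const double g = 1.0 / std::sqrt(3.0);
  vec::fixed<8> N; mat::fixed<8,3> dN;

  for (int e = 0; e < ne && ok; ++e) {
    mat::fixed<3,8> Xe, xe;
    for (int a = 0; a < 8; ++a) {
      int n0 = conn(e,a) - 1;
      Xe.col(a) = X.row(n0).t();
      for (int i = 0; i < 3; ++i)
        xe(i,a) = Xe(i,a) + uv[3*n0 + i];
    }
    vec3 f0c, s0c;
    for (int i = 0; i < 3; ++i) { f0c(i) = f0m(e,i); s0c(i) = s0m(e,i); }
    double tmax = tmax_el[e];

    vec::fixed<24> fe; fe.zeros();
    mat Ke(24, 24, fill::zeros);
    mat B(6, 24);

    // deviatoric + active at 2x2x2 Gauss points
    for (int q = 0; q < 8; ++q) {
      double xi = (q & 1) ? g : -g;
      double eta = (q & 2) ? g : -g;
      double ze = (q & 4) ? g : -g;
      hex_shape(xi, eta, ze, N, dN);
      mat33 J0 = Xe * dN;
      double detJ0 = det(J0);
      if (detJ0 <= 0.0) { ok = false; break; }
      mat::fixed<8,3> dNdX = dN * inv(J0);
      mat33 F = xe * dNdX;

      mat33 S; mat66 Dm; double psi;
      if (!ho_point(F, f0c, s0c, mp, tmax, ap, time,
                    true, false, want_tangent, S, Dm, psi)) { ok = false; break; }

      B.zeros();
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          int c = 3*a + i;
          B(0,c) = F(i,0) * dNdX(a,0);
          B(1,c) = F(i,1) * dNdX(a,1);
          B(2,c) = F(i,2) * dNdX(a,2);
          B(3,c) = F(i,0)*dNdX(a,1) + F(i,1)*dNdX(a,0);
          B(4,c) = F(i,0)*dNdX(a,2) + F(i,2)*dNdX(a,0);
          B(5,c) = F(i,1)*dNdX(a,2) + F(i,2)*dNdX(a,1);
        }
      vec::fixed<6> Sv = voigt(S);
      fe += (B.t() * Sv) * detJ0;
      psi_tot += psi * detJ0;
      if (want_tangent) {
        Ke += B.t() * Dm * B * detJ0;
        // geometric stiffness
        mat::fixed<8,8> G = dNdX * symmatu(S) * dNdX.t();
        for (int a = 0; a < 8; ++a)
          for (int b2 = 0; b2 < 8; ++b2) {
            double gg = G(a,b2) * detJ0;
            Ke(3*a,   3*b2)   += gg;
            Ke(3*a+1, 3*b2+1) += gg;
            Ke(3*a+2, 3*b2+2) += gg;
          }
      }
    }
    if (!ok) break;

    // volumetric penalty at the element center (selective reduced integration)
    {
      hex_shape(0.0, 0.0, 0.0, N, dN);
      mat33 J0 = Xe * dN;
      double detJ0 = det(J0);
      if (detJ0 <= 0.0) { ok = false; break; }
      double w = 8.0 * detJ0;
      mat::fixed<8,3> dNdX = dN * inv(J0);
      mat33 F = xe * dNdX;
      mat33 S; mat66 Dm; double psi;
      if (!ho_point(F, f0c, s0c, mp, 0.0, ap, -1.0,
                    false, true, want_tangent, S, Dm, psi)) { ok = false; break; }
      B.zeros();
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          int c = 3*a + i;
          B(0,c) = F(i,0) * dNdX(a,0);
          B(1,c) = F(i,1) * dNdX(a,1);
          B(2,c) = F(i,2) * dNdX(a,2);
          B(3,c) = F(i,0)*dNdX(a,1) + F(i,1)*dNdX(a,0);
          B(4,c) = F(i,0)*dNdX(a,2) + F(i,2)*dNdX(a,0);
          B(5,c) = F(i,1)*dNdX(a,2) + F(i,2)*dNdX(a,1);
        }
      vec::fixed<6> Sv = voigt(S);
      fe += (B.t() * Sv) * w;
      psi_tot += psi * w;
      if (want_tangent) {
        Ke += B.t() * Dm * B * w;
        mat::fixed<8,8> G = dNdX * symmatu(S) * dNdX.t();
        for (int a = 0; a < 8; ++a)
          for (int b2 = 0; b2 < 8; ++b2) {
            double gg = G(a,b2) * w;
            Ke(3*a,   3*b2)   += gg;
            Ke(3*a+1, 3*b2+1) += gg;
            Ke(3*a+2, 3*b2+2) += gg;
          }
      }
    }

    // scatter
    for (int a = 0; a < 8; ++a) {
      int n0 = conn(e,a) - 1;
      for (int i = 0; i < 3; ++i)
        fint[3*n0 + i] += fe(3*a + i);
    }
    if (want_tangent) {
      double* kp = &Kv[ (size_t)e * 576 ];
      for (int c = 0; c < 24; ++c)
        for (int r = 0; r < 24; ++r)
          *kp++ = Ke(r, c);
    }
  }

  return List::create(_["ok"] = ok, _["fint"] = fint, _["Kv"] = Kv,
                      _["psi"] = psi_tot);
}

// accumulate triplet values into a precomputed CSC value layout; pos is
// 1-based, 0 marks dropped (constrained) entries
// [[Rcpp::export(name = ".accum_pos_cpp")]]
NumericVector accum_pos_cpp(IntegerVector pos, NumericVector vals, int nnz) {
  NumericVector x(nnz);
  R_xlen_t n = pos.size();
  if (vals.size() != n) stop("pos/vals length mismatch");
  for (R_xlen_t k = 0; k < n; ++k) {
    int p = pos[k];
    if (p > 0) x[p - 1] += vals[k];
  }
  return x;
}

// ---------------------------------------------------------------------------
// follower pressure load on quadrilateral faces.
// Faces are oriented so that (x_,xi x x_,eta) is the cavity-outward normal
// (pointing from the cavity into the wall); the force on the structure for a
// cavity pressure p is then p * Phi with Phi = int N_a n dA.

// [[Rcpp::export(name = ".face_pattern_cpp")]]
List face_pattern_cpp(IntegerMatrix faces, int nnode) {
  int nf = faces.nrow();
  IntegerVector ti(nf * 144), tj(nf * 144);
  int k = 0;
  for (int f = 0; f < nf; ++f) {
    int dofs[12];
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        dofs[3*a + i] = 3 * (faces(f,a) - 1) + i + 1;
    for (int c = 0; c < 12; ++c)
      for (int r = 0; r < 12; ++r) {
        ti[k] = dofs[r]; tj[k] = dofs[c]; ++k;
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["ndof"] = 3 * nnode);
}

static inline mat33 skew3(const vec3& v) {
  mat33 W(fill::zeros);
  W(0,1) = -v(2); W(0,2) =  v(1);
  W(1,0) =  v(2); W(1,2) = -v(0);
  W(2,0) = -v(1); W(2,1) =  v(0);
  return W;
}

// [[Rcpp::export(name = ".face_load_cpp")]]
List face_load_cpp(NumericMatrix Xm, IntegerMatrix faces, NumericVector uv,
                   bool want_tangent) {
  int nf = faces.nrow();
  int nn = Xm.nrow();
  mat X(Xm.begin(), nn, 3);
  NumericVector Phi(3 * nn);
  NumericVector Kv(want_tangent ? nf * 144 : 0);

  const double g = 1.0 / std::sqrt(3.0);
  const double qx[4] = {-g, g, g, -g};
  const double qe[4] = {-g, -g, g, g};

  for (int f = 0; f < nf; ++f) {
    mat::fixed<3,4> xe;
    for (int a = 0; a < 4; ++a) {
      int n0 = faces(f,a) - 1;
      for (int i = 0; i < 3; ++i)
        xe(i,a) = X(n0, i) + uv[3*n0 + i];
    }
    vec::fixed<12> fe; fe.zeros();
    mat Kf(12, 12, fill::zeros);
    for (int q = 0; q < 4; ++q) {
      double xi = qx[q], eta = qe[q];
      double Nq[4] = {0.25*(1-xi)*(1-eta), 0.25*(1+xi)*(1-eta),
                      0.25*(1+xi)*(1+eta), 0.25*(1-xi)*(1+eta)};
      double dxi[4] = {-0.25*(1-eta), 0.25*(1-eta), 0.25*(1+eta), -0.25*(1+eta)};
      double det_[4] = {-0.25*(1-xi), -0.25*(1+xi), 0.25*(1+xi), 0.25*(1-xi)};
      vec3 txi(fill::zeros), teta(fill::zeros);
      for (int a = 0; a < 4; ++a) {
        txi  += dxi[a]  * xe.col(a);
        teta += det_[a] * xe.col(a);
      }
      vec3 nrm = cross(txi, teta);
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i)
          fe(3*a + i) += Nq[a] * nrm(i);
      if (want_tangent) {
        mat33 Wxi = skew3(txi), Weta = skew3(teta);
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b) {
            // d(txi x teta)/dx_b = -dxi_b * skew(teta) + deta_b * skew(txi)
            mat33 blk = (-dxi[b]) * Weta + det_[b] * Wxi;
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j)
                Kf(3*a + i, 3*b + j) += Nq[a] * blk(i, j);
          }
      }
    }
    for (int a = 0; a < 4; ++a) {
      int n0 = faces(f,a) - 1;
      for (int i = 0; i < 3; ++i)
        Phi[3*n0 + i] += fe(3*a + i);
    }
    if (want_tangent) {
      double* kp = &Kv[(size_t)f * 144];
      for (int c = 0; c < 12; ++c)
        for (int r = 0; r < 12; ++r)
          *kp++ = Kf(r, c);
    }
  }
  return List::create(_["Phi"] = Phi, _["Kv"] = Kv);
}

// ---------------------------------------------------------------------------
// cavity volume over an oriented closed triangulated surface (signed tets
// against a fixed reference point), plus its gradient wrt nodal positions.

// [[Rcpp::export(name = ".cavity_volume_cpp")]]
double cavity_volume_cpp(NumericMatrix Xm, IntegerMatrix tris, NumericVector uv,
                         NumericVector refpt) {
  int nt = tris.nrow();
  mat X(Xm.begin(), Xm.nrow(), 3);
  vec3 r0; for (int i = 0; i < 3; ++i) r0(i) = refpt[i];
  double V = 0.0;
  for (int t = 0; t < nt; ++t) {
    vec3 p[3];
    for (int a = 0; a < 3; ++a) {
      int n0 = tris(t,a) - 1;
      for (int i = 0; i < 3; ++i)
        p[a](i) = X(n0,i) + uv[3*n0 + i];
      p[a] -= r0;
    }
    V += dot(p[0], cross(p[1], p[2])) / 6.0;
  }
  return V;
}

// [[Rcpp::export(name = ".cavity_volume_grad_cpp")]]
NumericVector cavity_volume_grad_cpp(NumericMatrix Xm, IntegerMatrix tris,
                                     NumericVector uv, NumericVector refpt) {
  int nt = tris.nrow();
  int nn = Xm.nrow();
  mat X(Xm.begin(), nn, 3);
  vec3 r0; for (int i = 0; i < 3; ++i) r0(i) = refpt[i];
  NumericVector gr(3 * nn);
  for (int t = 0; t < nt; ++t) {
    int id[3];
    vec3 p[3];
    for (int a = 0; a < 3; ++a) {
      id[a] = tris(t,a) - 1;
      for (int i = 0; i < 3; ++i)
        p[a](i) = X(id[a],i) + uv[3*id[a] + i];
      p[a] -= r0;
    }
    vec3 g0 = cross(p[1], p[2]) / 6.0;
    vec3 g1 = cross(p[2], p[0]) / 6.0;
    vec3 g2 = cross(p[0], p[1]) / 6.0;
    for (int i = 0; i < 3; ++i) {
      gr[3*id[0] + i] += g0(i);
      gr[3*id[1] + i] += g1(i);
      gr[3*id[2] + i] += g2(i);
    }
  }
  return gr;
}

// Hessian of the cavity volume wrt nodal positions (pressure-load stiffness
// of the conservative fluid-cavity load F = p dV/dx). Per triangle only the
// six off-diagonal 3x3 node blocks are nonzero:
//   d2V/dr1 dr2 = -skew(r3)/6, d2V/dr1 dr3 = +skew(r2)/6, etc. (cyclic)

// [[Rcpp::export(name = ".cavity_hess_pattern_cpp")]]
List cavity_hess_pattern_cpp(IntegerMatrix tris, int nnode) {
  int nt = tris.nrow();
  IntegerVector ti(nt * 54), tj(nt * 54);
  int k = 0;
  for (int t = 0; t < nt; ++t) {
    int nd[3] = {tris(t,0) - 1, tris(t,1) - 1, tris(t,2) - 1};
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        if (a == b) continue;
        for (int cj = 0; cj < 3; ++cj)
          for (int ri = 0; ri < 3; ++ri) {
            ti[k] = 3 * nd[a] + ri + 1;
            tj[k] = 3 * nd[b] + cj + 1;
            ++k;
          }
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["ndof"] = 3 * nnode);
}

// [[Rcpp::export(name = ".cavity_hess_cpp")]]
NumericVector cavity_hess_cpp(NumericMatrix Xm, IntegerMatrix tris,
                              NumericVector uv, NumericVector refpt) {
  int nt = tris.nrow();
  mat X(Xm.begin(), Xm.nrow(), 3);
  vec3 r0; for (int i = 0; i < 3; ++i) r0(i) = refpt[i];
  NumericVector Hv(nt * 54);
  int k = 0;
  for (int t = 0; t < nt; ++t) {
    vec3 r[3];
    for (int a = 0; a < 3; ++a) {
      int n0 = tris(t,a) - 1;
      for (int i = 0; i < 3; ++i)
        r[a](i) = X(n0,i) + uv[3*n0 + i];
      r[a] -= r0;
    }
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        if (a == b) continue;
        // dV/dr_a = cross(r_{a+1}, r_{a+2})/6 (cyclic); differentiate wrt r_b
        int c = 3 - a - b;          // the remaining vertex
        // d/dr_b [r_{a+1} x r_{a+2}]:
        //   if b == a+1 (cyclic): result = -skew(r_c) ... sign depends on order
        mat33 blk;
        if (b == (a + 1) % 3) blk = -skew3(r[c]) / 6.0;  // r_b x r_c pattern
        else                  blk =  skew3(r[c]) / 6.0;
        for (int cj = 0; cj < 3; ++cj)
          for (int ri = 0; ri < 3; ++ri)
            Hv[k++] = blk(ri, cj);
      }
  }
  return Hv;
}

// ---------------------------------------------------------------------------
// per-element fields at the element center: deformation gradient, fiber
// Green-Lagrange strain (reference config), total Cauchy fiber stress, J.

// [[Rcpp::export(name = ".elem_fields_cpp")]]
List elem_fields_cpp(NumericMatrix Xm, IntegerMatrix conn,
                     NumericMatrix f0m, NumericMatrix s0m,
                     NumericVector uv, List matpar, NumericVector tmax_el,
                     List actpar, double time) {
  int ne = conn.nrow();
  mat X(Xm.begin(), Xm.nrow(), 3);
  MatP mp = matp_from_list(matpar);
  ActP ap = actp_from_list(actpar);
  NumericVector Eff(ne), sig_f(ne), Jv(ne), vol(ne);
  NumericMatrix Fm(ne, 9);
  vec::fixed<8> N; mat::fixed<8,3> dN;
  for (int e = 0; e < ne; ++e) {
    mat::fixed<3,8> Xe, xe;
    for (int a = 0; a < 8; ++a) {
      int n0 = conn(e,a) - 1;
      Xe.col(a) = X.row(n0).t();
      for (int i = 0; i < 3; ++i)
        xe(i,a) = Xe(i,a) + uv[3*n0 + i];
    }
    hex_shape(0.0, 0.0, 0.0, N, dN);
    mat33 J0 = Xe * dN;
    mat::fixed<8,3> dNdX = dN * inv(J0);
    mat33 F = xe * dNdX;
    vec3 f0c, s0c;
    for (int i = 0; i < 3; ++i) { f0c(i) = f0m(e,i); s0c(i) = s0m(e,i); }
    mat33 C = F.t() * F;
    double I4f = as_scalar(f0c.t() * C * f0c);
    Eff[e] = 0.5 * (I4f - 1.0);
    double J = det(F);
    Jv[e] = J;
    vol[e] = 8.0 * det(J0);
    mat33 S; mat66 Dm; double psi;
    ho_point(F, f0c, s0c, mp, tmax_el[e], ap, time, true, true, false, S, Dm, psi);
    mat33 sig = (F * symmatu(S) * F.t()) / J;
    vec3 fdef = F * f0c;
    fdef /= norm(fdef);
    sig_f[e] = as_scalar(fdef.t() * sig * fdef);
    for (int c = 0, k = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r)
        Fm(e, k++) = F(r, c);   // column-major flatten
  }
  return List::create(_["Eff"] = Eff, _["sigma_f"] = sig_f, _["J"] = Jv,
                      _["F"] = Fm, _["vol"] = vol);
}
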