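// Core finite-element kernels for quadratic (10-node) tetrahedral meshes:
// total-Lagrangian assembly of the Fung transversely isotropic law with a
// volumetric penalty and an active fiber stress, cavity-volume measures with
// displacement gradients (follower pressure loads), quadratic-triangle
// surface mass (epicardial Robin springs), and a scalar Laplace operator
// (transmural coordinate).
//
// Units: mm, kPa (stress), so forces are in mN and energies in uJ.
// Node ordering (internal): vertices 1-4, then midside nodes on edges
// (1,2),(2,3),(3,1),(1,4),(2,4),(3,4).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double QP_A = 0.5854101966249685;
static const double QP_B = 0.1381966011250105;

// 4-point degree-2 rule on the reference tetrahedron (weights sum to 1/6)
static void tet_quadrature(mat &pts, vec &w) {
  pts.set_size(4, 3);
  pts(0, 0) = QP_B; pts(0, 1) = QP_B; pts(0, 2) = QP_B;
  pts(1, 0) = QP_A; pts(1, 1) = QP_B; pts(1, 2) = QP_B;
  pts(2, 0) = QP_B; pts(2, 1) = QP_A; pts(2, 2) = QP_B;
  pts(3, 0) = QP_B; pts(3, 1) = QP_B; pts(3, 2) = QP_A;
  w.set_size(4);
  w.fill(1.0 / 24.0);
}

static void tet10_shape(double x, double y, double z, vec &N, mat &dN) {
  double L1 = 1.0 - x - y - z, L2 = x, L3 = y, L4 = z;
  N.set_size(10);
  N(0) = L1 * (2 * L1 - 1); N(1) = L2 * (2 * L2 - 1);
  N(2) = L3 * (2 * L3 - 1); N(3) = L4 * (2 * L4 - 1);
  N(4) = 4 * L1 * L2; N(5) = 4 * L2 * L3; N(6) = 4 * L3 * L1;
  N(7) = 4 * L1 * L4; N(8) = 4 * L2 * L4; N(9) = 4 * L3 * L4;
  // gradients of L: dL1 = (-1,-1,-1), dL2 = (1,0,0), dL3 = (0,1,0), dL4 = (0,0,1)
  dN.set_size(10, 3);
  rowvec d1 = {-1, -1, -1}, d2 = {1, 0, 0}, d3 = {0, 1, 0}, d4 = {0, 0, 1};
  dN.row(0) = (4 * L1 - 1) * d1;
  dN.row(1) = (4 * L2 - 1) * d2;
  dN.row(2) = (4 * L3 - 1) * d3;
  dN.row(3) = (4 * L4 - 1) * d4;
  dN.row(4) = 4 * (L2 * d1 + L1 * d2);
  dN.row(5) = 4 * (L3 * d2 + L2 * d3);
  dN.row(6) = 4 * (L1 * d3 + L3 * d1);
  dN.row(7) = 4 * (L4 * d1 + L1 * d4);
  dN.row(8) = 4 * (L4 * d2 + L2 * d4);
  dN.row(9) = 4 * (L4 * d3 + L3 * d4);
}

// 7-point degree-5 rule on the reference triangle (weights sum to 1/2)
static void tri_quadrature(mat &pts, vec &w) {
  double a = 0.0597158717897698, b = 0.4701420641051151;
  double c = 0.7974269853530873, d = 0.1012865073234563;
  pts.set_size(7, 2);
  w.set_size(7);
  pts(0, 0) = 1.0 / 3.0; pts(0, 1) = 1.0 / 3.0; w(0) = 0.225;
  pts(1, 0) = a; pts(1, 1) = b; w(1) = 0.1323941527885062;
  pts(2, 0) = b; pts(2, 1) = a; w(2) = 0.1323941527885062;
  pts(3, 0) = b; pts(3, 1) = b; w(3) = 0.1323941527885062;
  pts(4, 0) = c; pts(4, 1) = d; w(4) = 0.1259391805448271;
  pts(5, 0) = d; pts(5, 1) = c; w(5) = 0.1259391805448271;
  pts(6, 0) = d; pts(6, 1) = d; w(6) = 0.1259391805448271;
  w *= 0.5;
}

// TRI6: vertices 1-3, midsides on edges (1,2),(2,3),(3,1)
static void tri6_shape(double xi, double eta, vec &N, mat &dN) {
  double L1 = 1.0 - xi - eta, L2 = xi, L3 = eta;
  N.set_size(6);
  N(0) = L1 * (2 * L1 - 1); N(1) = L2 * (2 * L2 - 1); N(2) = L3 * (2 * L3 - 1);
  N(3) = 4 * L1 * L2; N(4) = 4 * L2 * L3; N(5) = 4 * L3 * L1;
  dN.set_size(6, 2);
  rowvec d1 = {-1, -1}, d2 = {1, 0}, d3 = {0, 1};
  dN.row(0) = (4 * L1 - 1) * d1;
  dN.row(1) = (4 * L2 - 1) * d2;
  dN.row(2) = (4 * L3 - 1) * d3;
  dN.row(3) = 4 * (L2 * d1 + L1 * d2);
  dN.row(4) = 4 * (L3 * d2 + L2 * d3);
  dN.row(5) = 4 * (L1 * d3 + L3 * d1);
}

// Fung strain energy and 2nd PK stress in the fiber frame.
// Efib: symmetric 3x3 Green-Lagrange strain in (f,s,n); B holds exponent
// coefficients per component. Returns W and fills Sfib, and the 9x9 tangent
// d(Sij)/d(Ekl) in flattened (column-major 3x3) ordering when requested.
static double fung_energy_stress(const mat33 &Efib, double Cc, double bff,
                                 double bxx, double bfx, double Qcap,
                                 mat33 &Sfib, mat *tang9, bool want_tang,
                                 bool &overflow) {
  mat33 B;
  B(0, 0) = bff; B(1, 1) = bxx; B(2, 2) = bxx;
  B(1, 2) = bxx; B(2, 1) = bxx;
  B(0, 1) = bfx; B(1, 0) = bfx; B(0, 2) = bfx; B(2, 0) = bfx;
  double Q = 0.0;
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) Q += B(i, j) * Efib(i, j) * Efib(i, j);
  if (Q > Qcap) { overflow = true; }
  double eQ = std::exp(std::min(Q, Qcap));
  double W = 0.5 * Cc * (eQ - 1.0);
  mat33 BE = B % Efib;          // elementwise
  Sfib = Cc * eQ * BE;
  if (want_tang) {
    // dS_ij/dE_kl = C eQ [ B_ij delta_ik delta_jl + 2 (BE)_ij (BE)_kl ]
    vec be = vectorise(BE);
    mat &T = *tang9;
    T = 2.0 * Cc * eQ * (be * be.t());
    vec bdiag = vectorise(B);
    for (int k = 0; k < 9; k++) T(k, k) += Cc * eQ * bdiag(k);
  }
  return W;
}

// Active fiber tension (kPa) as a function of fiber stretch lambda and cycle
// time t; Guccione-family calcium activation.
// par = (T0, Ca0, Ca0max, Blen, l0, lref, t, t0, m, btime)
static double active_tension(double lambda, const vec &par, bool &bad) {
  double T0 = par(0), Ca0 = par(1), Ca0max = par(2), Blen = par(3),
         l0 = par(4), lref = par(5), t = par(6), t0 = par(7), m = par(8),
         btime = par(9);
  if (T0 <= 0.0 || t < 0.0) return 0.0;
  double l = lref * lambda;
  double arg = std::exp(Blen * (l - l0)) - 1.0;
  // below the law's domain ECa50 -> infinity, so tension -> 0 continuously
  if (arg <= 0.0) return 0.0;
  double ECa50 = Ca0max / std::sqrt(arg);
  double tr = m * l + btime;
  if (tr <= 0.0) { bad = true; return 0.0; }
  double omega = 0.0;
  if (t >= 0.0 && t < t0) omega = M_PI * t / t0;
  else if (t >= t0 && t < t0 + tr) omega = M_PI * (t - t0 + tr) / tr;
  else omega = 0.0;
  double Ct = 0.5 * (1.0 - std::cos(omega));
  return T0 * Ca0 * Ca0 / (Ca0 * Ca0 + ECa50 * ECa50) * Ct;
}

// [[Rcpp::export]]
double active_tension_cpp(double lambda, const arma::vec &par) {
  bool bad = false;
  double v = active_tension(lambda, par, bad);
  if (bad) Rcpp::stop("active tension undefined (sarcomere length below law domain or t_r <= 0)");
  return v;
}

struct QPGeom {
  mat dNdX;     // 10 x 3
  double wdet;  // quadrature weight * reference Jacobian
};

static void element_qp_geometry(const mat &X, std::vector<QPGeom> &qps,
                                const mat &qpts, const vec &qw, bool &bad) {
  vec N; mat dN;
  qps.resize(qpts.n_rows);
  for (uword q = 0; q < qpts.n_rows; q++) {
    tet10_shape(qpts(q, 0), qpts(q, 1), qpts(q, 2), N, dN);
    mat33 J = X.t() * dN;  // dx/dxi
    double dJ = det(J);
    if (dJ <= 0) bad = true;
    qps[q].dNdX = dN * inv(J);
    qps[q].wdet = qw(q) * dJ;
  }
}

// Main assembly: residual (internal forces), optional tangent triplets, and
// per-quadrature-point diagnostics.
// pmat = (C, bff, bxx, bfx, kappa, Qcap); frames rows = (f, s, n) global.
// [[Rcpp::export]]
Rcpp::List fe_assemble(const arma::mat &nodes, const arma::imat &elems,
                       const arma::vec &U, const arma::mat &frames,
                       const arma::vec &pmat, const arma::vec &pact_par,
                       bool want_tangent) {
  const uword ne = elems.n_rows, nn = nodes.n_rows, nq = 4;
  mat qpts; vec qw; tet_quadrature(qpts, qw);
  double Cc = pmat(0), bff = pmat(1), bxx = pmat(2), bfx = pmat(3),
         kappa = pmat(4), Qcap = pmat(5);
  vec R(3 * nn, fill::zeros);
  std::vector<double> ti, tj, tx;
  if (want_tangent) { ti.reserve(ne * 900); tj.reserve(ne * 900); tx.reserve(ne * 900); }
  vec detF_qp(ne * nq), W_qp(ne * nq), wref_qp(ne * nq);
  double energy = 0.0;
  bool overflow = false, badgeom = false, badact = false;
  mat Ue(10, 3), Xe(10, 3);
  std::vector<QPGeom> qg;
  mat tang9(9, 9);
  mat::fixed<9, 9> RR, Cg9;
  mat::fixed<30, 9> D, DC;
  mat Ke(30, 30);

  for (uword e = 0; e < ne; e++) {
    for (int a = 0; a < 10; a++) {
      uword n = elems(e, a);
      Xe.row(a) = nodes.row(n);
      for (int i = 0; i < 3; i++) Ue(a, i) = U(3 * n + i);
    }
    element_qp_geometry(Xe, qg, qpts, qw, badgeom);
    if (want_tangent) Ke.zeros();
    vec fe(30, fill::zeros);

    for (uword q = 0; q < nq; q++) {
      const mat &dNdX = qg[q].dNdX;
      double w = qg[q].wdet;
      mat33 F = eye(3, 3) + Ue.t() * dNdX;
      mat33 Cg = F.t() * F;
      mat33 E = 0.5 * (Cg - eye(3, 3));
      double J = det(F);
      detF_qp(e * nq + q) = J;
      wref_qp(e * nq + q) = w;

      // rotation to fiber frame: columns f, s, n
      mat33 Rot;
      for (int i = 0; i < 3; i++) {
        Rot(i, 0) = frames(e * nq + q, i);
        Rot(i, 1) = frames(e * nq + q, 3 + i);
        Rot(i, 2) = frames(e * nq + q, 6 + i);
      }
      mat33 Efib = Rot.t() * E * Rot;
      mat33 Sfib;
      double W = fung_energy_stress(Efib, Cc, bff, bxx, bfx, Qcap, Sfib,
                                    want_tangent ? &tang9 : nullptr,
                                    want_tangent, overflow);
      mat33 S = Rot * Sfib * Rot.t();

      // volumetric penalty U(J) = kappa/2 (J-1)^2
      mat33 Cinv = inv(Cg);
      double Wvol = 0.5 * kappa * (J - 1.0) * (J - 1.0);
      S += kappa * (J - 1.0) * J * Cinv;
      W_qp(e * nq + q) = W + Wvol;
      energy += w * (W + Wvol);

      // active stress along reference fiber direction
      vec3 f = Rot.col(0);
      double lam = std::sqrt(dot(f, Cg * f));
      double Pa = 0.0, dPa = 0.0;
      if (pact_par(0) > 0.0 && pact_par(6) >= 0.0) {
        Pa = active_tension(lam, pact_par, badact);
        double h = 1e-6;
        double Pp = active_tension(lam + h, pact_par, badact);
        dPa = (Pp - Pa) / h;
        S += Pa * (f * f.t());
      }

      // internal force: P = F S ; f_a_i = w * P(i,:) . dNdX(a,:)
      mat33 P = F * S;
      for (int a = 0; a < 10; a++) {
        vec3 g = dNdX.row(a).t();
        vec3 fi = P * g;
        for (int i = 0; i < 3; i++) fe(3 * a + i) += w * fi(i);
      }

      if (want_tangent) {
        // material tangent in global frame, 9x9 flattened (col-major 3x3);
        // rotate the fiber-frame tangent via vec(R A R^T) = (R kron R) vec(A)
        for (int c1 = 0; c1 < 3; c1++) for (int c2 = 0; c2 < 3; c2++)
          for (int r1 = 0; r1 < 3; r1++) for (int r2 = 0; r2 < 3; r2++)
            RR(3 * c1 + r1, 3 * c2 + r2) = Rot(c1, c2) * Rot(r1, r2);
        Cg9 = RR * tang9 * RR.t();
        // volumetric tangent
        double kvol1 = kappa * (2.0 * J - 1.0) * J;
        double kvol2 = kappa * (J - 1.0) * J;
        for (int i = 0; i < 3; i++) for (int j2 = 0; j2 < 3; j2++)
          for (int k = 0; k < 3; k++) for (int l = 0; l < 3; l++)
            Cg9(i + 3 * j2, k + 3 * l) +=
              kvol1 * Cinv(i, j2) * Cinv(k, l) -
              kvol2 * (Cinv(i, k) * Cinv(j2, l) + Cinv(i, l) * Cinv(j2, k));
        // active tangent: rank-one dPa/dlambda
        if (Pa != 0.0 || dPa != 0.0) {
          vec3 fv = f;
          double cc = dPa / std::max(lam, 1e-12);
          for (int i = 0; i < 3; i++) for (int j2 = 0; j2 < 3; j2++)
            for (int k = 0; k < 3; k++) for (int l = 0; l < 3; l++)
              Cg9(i + 3 * j2, k + 3 * l) +=
                cc * fv(i) * fv(j2) * fv(k) * fv(l);
        }
        // D matrix: row per dof (a,i), columns 9: dE_MN for unit du(a,i)
        for (int a = 0; a < 10; a++) {
          for (int i = 0; i < 3; i++) {
            for (int M = 0; M < 3; M++) for (int N2 = 0; N2 < 3; N2++)
              D(3 * a + i, M + 3 * N2) =
                0.5 * (F(i, M) * dNdX(a, N2) + F(i, N2) * dNdX(a, M));
          }
        }
        DC = D * Cg9;
        Ke += w * (DC * D.t());
        // geometric stiffness: delta_ik g_a . S g_b
        mat GS = dNdX * S * dNdX.t();  // 10x10
        for (int a = 0; a < 10; a++) for (int b = 0; b < 10; b++) {
          double v = w * GS(a, b);
          for (int i = 0; i < 3; i++) Ke(3 * a + i, 3 * b + i) += v;
        }
      }
    }

    for (int a = 0; a < 10; a++) {
      uword na = elems(e, a);
      for (int i = 0; i < 3; i++) R(3 * na + i) += fe(3 * a + i);
    }
    if (want_tangent) {
      for (int a = 0; a < 10; a++) for (int i = 0; i < 3; i++) {
        uword ra = 3 * elems(e, a) + i;
        for (int b = 0; b < 10; b++) for (int j2 = 0; j2 < 3; j2++) {
          ti.push_back((double)(ra + 1));
          tj.push_back((double)(3 * elems(e, b) + j2 + 1));
          tx.push_back(Ke(3 * a + i, 3 * b + j2));
        }
      }
    }
  }
  if (badgeom) Rcpp::stop("non-positive element Jacobian encountered");
  if (overflow) Rcpp::stop("Fung exponent Q exceeded cap (excessive strain state)");
  if (badact) Rcpp::stop("active tension undefined at a quadrature point");

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("residual") = R, Rcpp::Named("detF") = detF_qp,
      Rcpp::Named("W") = W_qp, Rcpp::Named("wref") = wref_qp,
      Rcpp::Named("energy") = energy);
  if (want_tangent) {
    out["Ki"] = Rcpp::NumericVector(ti.begin(), ti.end());
    out["Kj"] = Rcpp::NumericVector(tj.begin(), tj.end());
    out["Kx"] = Rcpp::NumericVector(tx.begin(), tx.end());
  }
  return out;
}

// Per-quadrature-point deformation and stress fields for postprocessing.
// Returns F (9 cols), detF, W (passive + volumetric), Cauchy stress (9 cols,
// total incl. active), fiber-projected Cauchy stress, reference qp positions
// and weights.
// [[Rcpp::export]]
Rcpp::List fe_fields(const arma::mat &nodes, const arma::imat &elems,
                     const arma::vec &U, const arma::mat &frames,
                     const arma::vec &pmat, const arma::vec &pact_par) {
  const uword ne = elems.n_rows, nq = 4;
  mat qpts; vec qw; tet_quadrature(qpts, qw);
  double Cc = pmat(0), bff = pmat(1), bxx = pmat(2), bfx = pmat(3),
         kappa = pmat(4), Qcap = pmat(5);
  mat Fout(ne * nq, 9), sig_out(ne * nq, 9), xqp(ne * nq, 3);
  vec detF(ne * nq), Wout(ne * nq), Wvol(ne * nq), wref(ne * nq), sig_ff(ne * nq);
  bool overflow = false, badgeom = false, badact = false;
  mat Ue(10, 3), Xe(10, 3);
  std::vector<QPGeom> qg;
  vec N; mat dN;
  for (uword e = 0; e < ne; e++) {
    for (int a = 0; a < 10; a++) {
      uword n = elems(e, a);
      Xe.row(a) = nodes.row(n);
      for (int i = 0; i < 3; i++) Ue(a, i) = U(3 * n + i);
    }
    element_qp_geometry(Xe, qg, qpts, qw, badgeom);
    for (uword q = 0; q < nq; q++) {
      tet10_shape(qpts(q, 0), qpts(q, 1), qpts(q, 2), N, dN);
      xqp.row(e * nq + q) = (N.t() * Xe);
      mat33 F = eye(3, 3) + Ue.t() * qg[q].dNdX;
      mat33 Cg = F.t() * F;
      mat33 E = 0.5 * (Cg - eye(3, 3));
      double J = det(F);
      mat33 Rot;
      for (int i = 0; i < 3; i++) {
        Rot(i, 0) = frames(e * nq + q, i);
        Rot(i, 1) = frames(e * nq + q, 3 + i);
        Rot(i, 2) = frames(e * nq + q, 6 + i);
      }
      mat33 Efib = Rot.t() * E * Rot;
      mat33 Sfib;
      double W = fung_energy_stress(Efib, Cc, bff, bxx, bfx, 1e30, Sfib,
                                    nullptr, false, overflow);
      mat33 S = Rot * Sfib * Rot.t();
      mat33 Cinv = inv(Cg);
      S += kappa * (J - 1.0) * J * Cinv;
      vec3 f = Rot.col(0);
      double lam = std::sqrt(dot(f, Cg * f));
      if (pact_par(0) > 0.0 && pact_par(6) >= 0.0)
        S += active_tension(lam, pact_par, badact) * (f * f.t());
      mat33 sig = (F * S * F.t()) / J;
      vec3 fdef = F * f; fdef /= norm(fdef);
      uword r = e * nq + q;
      for (int i = 0; i < 3; i++) for (int j2 = 0; j2 < 3; j2++) {
        Fout(r, i + 3 * j2) = F(i, j2);
        sig_out(r, i + 3 * j2) = sig(i, j2);
      }
      detF(r) = J;
      Wout(r) = W;
      Wvol(r) = 0.5 * kappa * (J - 1.0) * (J - 1.0);
      wref(r) = qg[q].wdet;
      sig_ff(r) = dot(fdef, sig * fdef);
    }
  }
  if (badgeom) Rcpp::stop("non-positive element Jacobian encountered");
  if (badact) Rcpp::stop("active tension undefined at a quadrature point");
  return Rcpp::List::create(
      Rcpp::Named("F") = Fout, Rcpp::Named("detF") = detF,
      Rcpp::Named("W") = Wout, Rcpp::Named("Wvol") = Wvol,
      Rcpp::Named("cauchy") = sig_out,
      Rcpp::Named("sigma_ff") = sig_ff, Rcpp::Named("x") = xqp,
      Rcpp::Named("wref") = wref);
}

// Relative Green-Lagrange strain of state 2 with state 1 as reference:
// E = 0.5 (Frel' Frel - I), Frel = F2 inv(F1), per quadrature point
// (rows are column-major flattened 3x3).
// [[Rcpp::export]]
arma::mat rel_strain_cpp(const arma::mat &F1, const arma::mat &F2) {
  const uword n = F1.n_rows;
  mat out(n, 9);
  mat33 A, B2, Frel, E;
  for (uword r = 0; r < n; r++) {
    for (int i = 0; i < 3; i++) for (int j = 0; j < 3; j++) {
      A(i, j) = F1(r, i + 3 * j);
      B2(i, j) = F2(r, i + 3 * j);
    }
    Frel = B2 * inv(A);
    E = 0.5 * (Frel.t() * Frel - eye(3, 3));
    for (int i = 0; i < 3; i++) for (int j = 0; j < 3; j++)
      out(r, i + 3 * j) = E(i, j);
  }
  return out;
}

// Cavity volume enclosed by a quadratic-triangle surface (plus an implicit
// flat cap on the z=0 base plane, which contributes nothing to the x.n flux)
// with optional gradient w.r.t. nodal displacements.
// [[Rcpp::export]]
Rcpp::List cavity_volume_grad(const arma::mat &nodes, const arma::imat &faces,
                              const arma::vec &U, bool want_grad) {
  mat qpts; vec qw; tri_quadrature(qpts, qw);
  const uword nf = faces.n_rows, nn = nodes.n_rows;
  double V = 0.0;
  vec grad;
  if (want_grad) grad.zeros(3 * nn);
  vec N; mat dN;
  mat Xe(6, 3);
  for (uword f = 0; f < nf; f++) {
    for (int a = 0; a < 6; a++) {
      uword n = faces(f, a);
      for (int i = 0; i < 3; i++) Xe(a, i) = nodes(n, i) + U(3 * n + i);
    }
    for (uword q = 0; q < qpts.n_rows; q++) {
      tri6_shape(qpts(q, 0), qpts(q, 1), N, dN);
      vec3 x = Xe.t() * N;
      vec3 g1 = Xe.t() * dN.col(0);
      vec3 g2 = Xe.t() * dN.col(1);
      vec3 cr = cross(g1, g2);
      V += qw(q) * dot(x, cr) / 3.0;
      if (want_grad) {
        vec3 c1 = cross(g2, x);   // d/dg1 of x.(g1 x g2) = g2 x x
        vec3 c2 = cross(x, g1);
        for (int a = 0; a < 6; a++) {
          uword n = faces(f, a);
          for (int i = 0; i < 3; i++)
            grad(3 * n + i) += qw(q) / 3.0 *
              (N(a) * cr(i) + dN(a, 0) * c1(i) + dN(a, 1) * c2(i));
        }
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("volume") = V);
  if (want_grad) out["grad"] = grad;
  return out;
}

// Hessian of the enclosed cavity volume w.r.t. nodal displacements (the
// follower-load stiffness of pressure loading through the volume
// constraint). Symmetric; returned as triplets into the 3N displacement
// space (1-based indices).
// [[Rcpp::export]]
Rcpp::List cavity_volume_hess(const arma::mat &nodes, const arma::imat &faces,
                              const arma::vec &U) {
  mat qpts; vec qw; tri_quadrature(qpts, qw);
  const uword nf = faces.n_rows;
  std::vector<double> hi, hj, hx;
  hi.reserve(nf * 324); hj.reserve(nf * 324); hx.reserve(nf * 324);
  vec N; mat dN;
  mat Xe(6, 3);
  // Levi-Civita
  auto eps = [](int i, int j, int k) -> double {
    if (i == j || j == k || i == k) return 0.0;
    if ((i == 0 && j == 1 && k == 2) || (i == 1 && j == 2 && k == 0) ||
        (i == 2 && j == 0 && k == 1)) return 1.0;
    return -1.0;
  };
  for (uword f = 0; f < nf; f++) {
    for (int a = 0; a < 6; a++) {
      uword n = faces(f, a);
      for (int i = 0; i < 3; i++) Xe(a, i) = nodes(n, i) + U(3 * n + i);
    }
    mat He(18, 18, fill::zeros);
    for (uword q = 0; q < qpts.n_rows; q++) {
      tri6_shape(qpts(q, 0), qpts(q, 1), N, dN);
      vec3 x = Xe.t() * N;
      vec3 g1 = Xe.t() * dN.col(0);
      vec3 g2 = Xe.t() * dN.col(1);
      double w3 = qw(q) / 3.0;
      for (int a = 0; a < 6; a++) for (int b = 0; b < 6; b++) {
        double c12 = dN(a, 0) * dN(b, 1) - dN(b, 0) * dN(a, 1);
        for (int i = 0; i < 3; i++) for (int j = 0; j < 3; j++) {
          double s = 0.0;
          for (int k = 0; k < 3; k++) {
            double e3 = eps(i, j, k);
            if (e3 == 0.0) continue;
            s += e3 * (N(a) * (dN(b, 0) * g2(k) - dN(b, 1) * g1(k)) -
                       N(b) * (dN(a, 0) * g2(k) - dN(a, 1) * g1(k)) +
                       c12 * x(k));
          }
          He(3 * a + i, 3 * b + j) += w3 * s;
        }
      }
    }
    for (int a = 0; a < 6; a++) for (int b = 0; b < 6; b++)
      for (int i = 0; i < 3; i++) for (int j = 0; j < 3; j++) {
        hi.push_back((double)(3 * faces(f, a) + i + 1));
        hj.push_back((double)(3 * faces(f, b) + j + 1));
        hx.push_back(He(3 * a + i, 3 * b + j));
      }
  }
  return Rcpp::List::create(
      Rcpp::Named("i") = Rcpp::NumericVector(hi.begin(), hi.end()),
      Rcpp::Named("j") = Rcpp::NumericVector(hj.begin(), hj.end()),
      Rcpp::Named("x") = Rcpp::NumericVector(hx.begin(), hx.end()));
}

// Surface mass matrix (scalar, reference configuration) over TRI6 faces.
// [[Rcpp::export]]
Rcpp::List tri6_mass(const arma::mat &nodes, const arma::imat &faces) {
  mat qpts; vec qw; tri_quadrature(qpts, qw);
  const uword nf = faces.n_rows;
  std::vector<double> mi, mj, mx;
  mi.reserve(nf * 36); mj.reserve(nf * 36); mx.reserve(nf * 36);
  double area = 0.0;
  vec N; mat dN;
  mat Xe(6, 3);
  for (uword f = 0; f < nf; f++) {
    for (int a = 0; a < 6; a++) Xe.row(a) = nodes.row(faces(f, a));
    mat Me(6, 6, fill::zeros);
    for (uword q = 0; q < qpts.n_rows; q++) {
      tri6_shape(qpts(q, 0), qpts(q, 1), N, dN);
      vec3 g1 = Xe.t() * dN.col(0);
      vec3 g2 = Xe.t() * dN.col(1);
      double dA = norm(cross(g1, g2));
      area += qw(q) * dA;
      Me += qw(q) * dA * (N * N.t());
    }
    for (int a = 0; a < 6; a++) for (int b = 0; b < 6; b++) {
      mi.push_back((double)(faces(f, a) + 1));
      mj.push_back((double)(faces(f, b) + 1));
      mx.push_back(Me(a, b));
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("i") = Rcpp::NumericVector(mi.begin(), mi.end()),
      Rcpp::Named("j") = Rcpp::NumericVector(mj.begin(), mj.end()),
      Rcpp::Named("x") = Rcpp::NumericVector(mx.begin(), mx.end()),
      Rcpp::Named("area") = area);
}

// Scalar Laplace stiffness on TET10 elements.
// [[Rcpp::export]]
Rcpp::List tet10_laplace(const arma::mat &nodes, const arma::imat &elems) {
  const uword ne = elems.n_rows;
  mat qpts; vec qw; tet_quadrature(qpts, qw);
  std::vector<double> ki, kj, kx;
  ki.reserve(ne * 100); kj.reserve(ne * 100); kx.reserve(ne * 100);
  bool bad = false;
  mat Xe(10, 3);
  std::vector<QPGeom> qg;
  for (uword e = 0; e < ne; e++) {
    for (int a = 0; a < 10; a++) Xe.row(a) = nodes.row(elems(e, a));
    element_qp_geometry(Xe, qg, qpts, qw, bad);
    mat Ke(10, 10, fill::zeros);
    for (uword q = 0; q < qpts.n_rows; q++)
      Ke += qg[q].wdet * (qg[q].dNdX * qg[q].dNdX.t());
    for (int a = 0; a < 10; a++) for (int b = 0; b < 10; b++) {
      ki.push_back((double)(elems(e, a) + 1));
      kj.push_back((double)(elems(e, b) + 1));
      kx.push_back(Ke(a, b));
    }
  }
  if (bad) Rcpp::stop("non-positive element Jacobian encountered");
  return Rcpp::List::create(
      Rcpp::Named("i") = Rcpp::NumericVector(ki.begin(), ki.end()),
      Rcpp::Named("j") = Rcpp::NumericVector(kj.begin(), kj.end()),
      Rcpp::Named("x") = Rcpp::NumericVector(kx.begin(), kx.end()));
}

// Scalar nodal field and its gradient evaluated at the tet quadrature points,
// plus reference qp positions and weights.
// [[Rcpp::export]]
Rcpp::List tet10_scalar_qp(const arma::mat &nodes, const arma::imat &elems,
                           const arma::vec &phi) {
  const uword ne = elems.n_rows, nq = 4;
  mat qpts; vec qw; tet_quadrature(qpts, qw);
  vec val(ne * nq), wref(ne * nq);
  mat grad(ne * nq, 3), xqp(ne * nq, 3);
  bool bad = false;
  mat Xe(10, 3);
  vec pe(10), N; mat dN;
  std::vector<QPGeom> qg;
  for (uword e = 0; e < ne; e++) {
    for (int a = 0; a < 10; a++) {
      Xe.row(a) = nodes.row(elems(e, a));
      pe(a) = phi(elems(e, a));
    }
    element_qp_geometry(Xe, qg, qpts, qw, bad);
    for (uword q = 0; q < nq; q++) {
      tet10_shape(qpts(q, 0), qpts(q, 1), qpts(q, 2), N, dN);
      uword r = e * nq + q;
      val(r) = dot(N, pe);
      grad.row(r) = (qg[q].dNdX.t() * pe).t();
      xqp.row(r) = (N.t() * Xe);
      wref(r) = qg[q].wdet;
    }
  }
  if (bad) Rcpp::stop("non-positive element Jacobian encountered");
  return Rcpp::List::create(
      Rcpp::Named("value") = val, Rcpp::Named("grad") = grad,
      Rcpp::Named("x") = xqp, Rcpp::Named("wref") = wref);
}

// Minimum corner/qp Jacobian determinant per element (mesh validity).
// [[Rcpp::export]]
arma::vec tet10_min_jacobian(const arma::mat &nodes, const arma::imat &elems) {
  const uword ne = elems.n_rows;
  // corners + quadrature points of the reference element
  mat pts(8, 3);
  pts(0, 0) = 0; pts(0, 1) = 0; pts(0, 2) = 0;
  pts(1, 0) = 1; pts(1, 1) = 0; pts(1, 2) = 0;
  pts(2, 0) = 0; pts(2, 1) = 1; pts(2, 2) = 0;
  pts(3, 0) = 0; pts(3, 1) = 0; pts(3, 2) = 1;
  mat qpts; vec qw; tet_quadrature(qpts, qw);
  pts.rows(4, 7) = qpts;
  vec out(ne);
  mat Xe(10, 3);
  vec N; mat dN;
  for (uword e = 0; e < ne; e++) {
    for (int a = 0; a < 10; a++) Xe.row(a) = nodes.row(elems(e, a));
    double mn = datum::inf;
    for (uword p = 0; p < pts.n_rows; p++) {
      tet10_shape(pts(p, 0), pts(p, 1), pts(p, 2), N, dN);
      mn = std::min(mn, det(Xe.t() * dN));
    }
    out(e) = mn;
  }
  return out;
}
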