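// Total-Lagrangian assembly for 4/10-node tetrahedra with an uncoupled
// Neo-Hookean material:  Psi = C1*(I1bar - 3) + 0.5*K*(ln J)^2.
// Returns internal force, tangent triplets and per-element J statistics.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Shape functions / natural derivatives. Node ordering (VTK):
// vertices 0..3, then mid-edge (0,1),(1,2),(0,2),(0,3),(1,3),(2,3).
static void tet_shape(int nn, double xi, double eta, double zeta,
                      vec &N, mat &dN) {
  double L0 = 1.0 - xi - eta - zeta, L1 = xi, L2 = eta, L3 = zeta;
  // dL/d(xi,eta,zeta)
  rowvec dL0 = {-1.0, -1.0, -1.0};
  rowvec dL1 = {1.0, 0.0, 0.0};
  rowvec dL2 = {0.0, 1.0, 0.0};
  rowvec dL3 = {0.0, 0.0, 1.0};
  if (nn == 4) {
    N = {L0, L1, L2, L3};
    dN.set_size(4, 3);
    dN.row(0) = dL0; dN.row(1) = dL1; dN.row(2) = dL2; dN.row(3) = dL3;
    return;
  }
  N.set_size(10); dN.set_size(10, 3);
  N(0) = L0 * (2.0 * L0 - 1.0);
  N(1) = L1 * (2.0 * L1 - 1.0);
  N(2) = L2 * (2.0 * L2 - 1.0);
  N(3) = L3 * (2.0 * L3 - 1.0);
  N(4) = 4.0 * L0 * L1;
  N(5) = 4.0 * L1 * L2;
  N(6) = 4.0 * L0 * L2;
  N(7) = 4.0 * L0 * L3;
  N(8) = 4.0 * L1 * L3;
  N(9) = 4.0 * L2 * L3;
  dN.row(0) = (4.0 * L0 - 1.0) * dL0;
  dN.row(1) = (4.0 * L1 - 1.0) * dL1;
  dN.row(2) = (4.0 * L2 - 1.0) * dL2;
  dN.row(3) = (4.0 * L3 - 1.0) * dL3;
  dN.row(4) = 4.0 * (L1 * dL0 + L0 * dL1);
  dN.row(5) = 4.0 * (L2 * dL1 + L1 * dL2);
  dN.row(6) = 4.0 * (L2 * dL0 + L0 * dL2);
  dN.row(7) = 4.0 * (L3 * dL0 + L0 * dL3);
  dN.row(8) = 4.0 * (L3 * dL1 + L1 * dL3);
  dN.row(9) = 4.0 * (L3 * dL2 + L2 * dL3);
}

// Quadrature: 1-point (tet4) or 4-point (tet10), weights sum to 1/6.
static void tet_quadrature(int nn, mat &pts, vec &w) {
  if (nn == 4) {
    pts = mat(1, 3); pts.row(0) = rowvec({0.25, 0.25, 0.25});
    w = vec({1.0 / 6.0});
    return;
  }
  const double a = 0.5854101966249685, b = 0.1381966011250105;
  pts = { {b, b, b}, {a, b, b}, {b, a, b}, {b, b, a} };
  w = vec(4); w.fill(1.0 / 24.0);
}

// Second Piola-Kirchhoff stress and material tangent CC (3x3x3x3,
// stored as cube slices CC[I][J](K,L)) at a given C = F'F.
static void neo_hookean_SC(const mat33 &C, double c1, double kbulk,
                           double J, mat33 &S, double CC[3][3][3][3]) {
  const double mu = 2.0 * c1;
  mat33 Cinv = inv_sympd(symmatu(C));
  double I1 = trace(C);
  double lnJ = std::log(J);
  double Jm23 = std::pow(J, -2.0 / 3.0);
  mat33 I3 = eye(3, 3);
  S = mu * Jm23 * (I3 - (I1 / 3.0) * Cinv) + kbulk * lnJ * Cinv;
  const double c_iso = 2.0 * mu * Jm23;
  for (int I = 0; I < 3; I++)
    for (int Jj = 0; Jj < 3; Jj++)
      for (int K = 0; K < 3; K++)
        for (int L = 0; L < 3; L++) {
          double IC = 0.5 * (Cinv(I, K) * Cinv(Jj, L) +
                             Cinv(I, L) * Cinv(Jj, K));
          double CiCi = Cinv(I, Jj) * Cinv(K, L);
          double iso = c_iso * ((I1 / 3.0) * IC + (I1 / 9.0) * CiCi -
                                (Cinv(I, Jj) * I3(K, L) +
                                 I3(I, Jj) * Cinv(K, L)) / 3.0);
          double vol = kbulk * CiCi - 2.0 * kbulk * lnJ * IC;
          CC[I][Jj][K][L] = iso + vol;
        }
}

// [[Rcpp::export]]
Rcpp::List tc_assemble_core(const arma::mat &nodes,      // n x 3
                            const arma::imat &elems,     // ne x nn (1-based)
                            const arma::vec &u,          // 3n
                            double c1, double kbulk,
                            bool want_tangent) {
  const int n = nodes.n_rows, ne = elems.n_rows, nn = elems.n_cols;
  if (nn != 4 && nn != 10) Rcpp::stop("elements must have 4 or 10 nodes");
  mat qp; vec qw;
  tet_quadrature(nn, qp, qw);
  const int nq = qp.n_rows, ndof = 3 * nn;

  vec fint(3 * n, fill::zeros);
  vec Jmean(ne, fill::zeros), Jdev(ne, fill::zeros);
  double energy = 0.0;
  bool ok = true;

  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    ti.reserve((size_t)ne * ndof * ndof);
    tj.reserve((size_t)ne * ndof * ndof);
    tx.reserve((size_t)ne * ndof * ndof);
  }

  vec N; mat dN;
  mat Xe(nn, 3), Ue(nn, 3), dNdX(nn, 3);
  mat Ke(ndof, ndof);
  vec fe(ndof);
  double CC[3][3][3][3];

  for (int e = 0; e < ne && ok; e++) {
    for (int a = 0; a < nn; a++) {
      int node = elems(e, a) - 1;
      Xe.row(a) = nodes.row(node);
      for (int i = 0; i < 3; i++) Ue(a, i) = u(3 * node + i);
    }
    fe.zeros();
    if (want_tangent) Ke.zeros();
    double wsum = 0.0, Jsum = 0.0, Jdmax = 0.0;

    for (int q = 0; q < nq; q++) {
      tet_shape(nn, qp(q, 0), qp(q, 1), qp(q, 2), N, dN);
      mat33 Jref = Xe.t() * dN;         // dX/dxi
      double detJ = det(Jref);
      if (detJ <= 0.0) { ok = false; break; }
      dNdX = dN * inv(Jref);            // nn x 3
      mat33 F = eye(3, 3) + Ue.t() * dNdX;
      double J = det(F);
      double w = qw(q) * detJ;
      wsum += w;
      if (J <= 0.0) { ok = false; Jdmax = datum::inf; break; }
      Jsum += w * J;
      Jdmax = std::max(Jdmax, std::abs(J - 1.0));
      mat33 C = F.t() * F;
      mat33 S;
      neo_hookean_SC(C, c1, kbulk, J, S, CC);
      double I1bar = std::pow(J, -2.0 / 3.0) * trace(C);
      double lnJ = std::log(J);
      energy += w * (c1 * (I1bar - 3.0) + 0.5 * kbulk * lnJ * lnJ);

      mat P = F * S;                    // first Piola
      for (int a = 0; a < nn; a++)
        for (int i = 0; i < 3; i++) {
          double s = 0.0;
          for (int Jj = 0; Jj < 3; Jj++) s += P(i, Jj) * dNdX(a, Jj);
          fe(3 * a + i) += w * s;
        }

      if (want_tangent) {
        // M[i][Jm][m][L] = F_iI CC_IJKL F_mK
        double M[3][3][3][3];
        for (int i = 0; i < 3; i++)
          for (int Jj = 0; Jj < 3; Jj++)
            for (int m = 0; m < 3; m++)
              for (int L = 0; L < 3; L++) {
                double s = 0.0;
                for (int I = 0; I < 3; I++)
                  for (int K = 0; K < 3; K++)
                    s += F(i, I) * CC[I][Jj][K][L] * F(m, K);
                M[i][Jj][m][L] = s;
              }
        for (int a = 0; a < nn; a++)
          for (int b = 0; b < nn; b++) {
            // geometric part
            double g = 0.0;
            for (int Jj = 0; Jj < 3; Jj++)
              for (int L = 0; L < 3; L++)
                g += dNdX(a, Jj) * S(Jj, L) * dNdX(b, L);
            for (int i = 0; i < 3; i++) {
              Ke(3 * a + i, 3 * b + i) += w * g;
              for (int m = 0; m < 3; m++) {
                double s = 0.0;
                for (int Jj = 0; Jj < 3; Jj++)
                  for (int L = 0; L < 3; L++)
                    s += dNdX(a, Jj) * M[i][Jj][m][L] * dNdX(b, L);
                Ke(3 * a + i, 3 * b + m) += w * s;
              }
            }
          }
      }
    }
    if (!ok) break;
    Jmean(e) = Jsum / wsum;
    Jdev(e) = Jdmax;

    for (int a = 0; a < nn; a++) {
      int na = elems(e, a) - 1;
      for (int i = 0; i < 3; i++) fint(3 * na + i) += fe(3 * a + i);
    }
    if (want_tangent) {
      for (int a = 0; a < nn; a++) {
        int na = elems(e, a) - 1;
        for (int b = 0; b < nn; b++) {
          int nb = elems(e, b) - 1;
          for (int i = 0; i < 3; i++)
            for (int m = 0; m < 3; m++) {
              ti.push_back(3 * na + i + 1);
              tj.push_back(3 * nb + m + 1);
              tx.push_back(Ke(3 * a + i, 3 * b + m));
            }
        }
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("ok") = ok,
      Rcpp::Named("fint") = fint,
      Rcpp::Named("energy") = energy,
      Rcpp::Named("J_mean") = Jmean,
      Rcpp::Named("J_dev") = Jdev);
  if (want_tangent) {
    out["k_i"] = Rcpp::IntegerVector(ti.begin(), ti.end());
    out["k_j"] = Rcpp::IntegerVector(tj.begin(), tj.end());
    out["k_x"] = Rcpp::NumericVector(tx.begin(), tx.end());
  }
  return out;
}

// Quadrature-averaged Cauchy stress per element (Voigt xx,yy,zz,xy,yz,xz).
// [[Rcpp::export]]
Rcpp::List tc_element_stress_core(const arma::mat &nodes,
                                  const arma::imat &elems,
                                  const arma::vec &u,
                                  double c1, double kbulk) {
  const int ne = elems.n_rows, nn = elems.n_cols;
  mat qp; vec qw;
  tet_quadrature(nn, qp, qw);
  const int nq = qp.n_rows;
  mat stress(ne, 6, fill::zeros);
  vec Jout(ne, fill::zeros);
  bool ok = true;
  vec N; mat dN;
  mat Xe(nn, 3), Ue(nn, 3);
  const double mu = 2.0 * c1;

  for (int e = 0; e < ne && ok; e++) {
    for (int a = 0; a < nn; a++) {
      int node = elems(e, a) - 1;
      Xe.row(a) = nodes.row(node);
      for (int i = 0; i < 3; i++) Ue(a, i) = u(3 * node + i);
    }
    double wsum = 0.0, Jsum = 0.0;
    mat33 sig(fill::zeros);
    for (int q = 0; q < nq; q++) {
      tet_shape(nn, qp(q, 0), qp(q, 1), qp(q, 2), N, dN);
      mat33 Jref = Xe.t() * dN;
      double detJ = det(Jref);
      if (detJ <= 0.0) { ok = false; break; }
      mat dNdX = dN * inv(Jref);
      mat33 F = eye(3, 3) + Ue.t() * dNdX;
      double J = det(F);
      if (J <= 0.0) { ok = false; break; }
      mat33 b = F * F.t();
      mat33 bbar = std::pow(J, -2.0 / 3.0) * b;
      mat33 dev_b = bbar - (trace(bbar) / 3.0) * eye(3, 3);
      mat33 s = (mu / J) * dev_b + (kbulk * std::log(J) / J) * eye(3, 3);
      double w = qw(q) * detJ;
      sig += w * s;
      Jsum += w * J;
      wsum += w;
    }
    if (!ok) break;
    sig /= wsum;
    Jout(e) = Jsum / wsum;
    stress(e, 0) = sig(0, 0); stress(e, 1) = sig(1, 1);
    stress(e, 2) = sig(2, 2); stress(e, 3) = sig(0, 1);
    stress(e, 4) = sig(1, 2); stress(e, 5) = sig(0, 2);
  }
  return Rcpp::List::create(Rcpp::Named("ok") = ok,
                            Rcpp::Named("stress") = stress,
                            Rcpp::Named("J") = Jout);
}
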