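// Element kernels for the plane-strain cross-section solver.
//
// Total-Lagrangian Q1 quadrilaterals with selective reduced integration:
// the isotropic matrix + fiber response is integrated at 2x2 Gauss points,
// the volumetric penalty (K/2)(J-1)^2 at the element centroid only, which
// avoids volumetric locking at K ~ 1e4 * C10 (2D counterpart of hybrid
// reduced-integration bricks). Hot loops use plain C arrays.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double EXP_CAP = 200.0; // k2*E^2 beyond this: flag, let Newton backtrack

struct PointState {
  double S[3];   // 2nd PK in-plane, Voigt (S11, S22, S12)
  double CC[3][3]; // material tangent 4 d2Psi/dC2, Voigt on (11,22,12) pairs
  double J;
  double energy;
  bool ok;
};

// Evaluate S, CC (minor-symmetric Voigt form) and energy at one point.
// parts: 1 = iso+fiber only, 2 = volumetric only, 3 = both.
// C given as (C11, C22, C12); tref as (t1, t2).
static inline PointState point_eval(const double C[3], double J,
                                    double c10, double k1, double k2,
                                    double kappa, double ca2,
                                    const double tref[2], double Kvol,
                                    int parts) {
  PointState ps;
  ps.S[0] = ps.S[1] = ps.S[2] = 0.0;
  for (int i = 0; i < 3; i++) for (int j = 0; j < 3; j++) ps.CC[i][j] = 0.0;
  ps.energy = 0.0;
  ps.J = J;
  ps.ok = (J > 0.0);
  if (!ps.ok) return ps;

  double det = C[0] * C[1] - C[2] * C[2];
  double Ci[3] = {C[1] / det, C[0] / det, -C[2] / det};

  if (parts & 1) {
    double I1 = C[0] + C[1] + 1.0;     // out-of-plane stretch fixed at 1
    double tCt = tref[0] * tref[0] * C[0] + tref[1] * tref[1] * C[1]
      + 2.0 * tref[0] * tref[1] * C[2];
    double I4 = ca2 * tCt + (1.0 - ca2);
    double E = kappa * (I1 - 3.0) + (1.0 - 3.0 * kappa) * (I4 - 1.0);

    // compressible neo-Hookean matrix: c10 (I1 - 3) - 2 c10 ln J keeps the
    // reference state stress-free under the penalty formulation
    ps.S[0] += 2.0 * c10 * (1.0 - Ci[0]);
    ps.S[1] += 2.0 * c10 * (1.0 - Ci[1]);
    ps.S[2] += -2.0 * c10 * Ci[2];
    // CC_IJKL += 2 c10 (Ci_IK Ci_JL + Ci_IL Ci_JK), Voigt-condensed
    {
      double c = 2.0 * c10;
      ps.CC[0][0] += c * 2.0 * Ci[0] * Ci[0];
      ps.CC[1][1] += c * 2.0 * Ci[1] * Ci[1];
      ps.CC[0][1] += c * 2.0 * Ci[2] * Ci[2];
      ps.CC[1][0] += c * 2.0 * Ci[2] * Ci[2];
      ps.CC[0][2] += c * 2.0 * Ci[0] * Ci[2];
      ps.CC[2][0] += c * 2.0 * Ci[0] * Ci[2];
      ps.CC[1][2] += c * 2.0 * Ci[1] * Ci[2];
      ps.CC[2][1] += c * 2.0 * Ci[1] * Ci[2];
      ps.CC[2][2] += c * (Ci[0] * Ci[1] + Ci[2] * Ci[2]);
    }
    ps.energy += c10 * (I1 - 3.0) - 2.0 * c10 * std::log(J);

    if (E > 0.0 && k1 > 0.0) {
      double arg = k2 * E * E;
      if (arg > EXP_CAP) { ps.ok = false; return ps; }
      double ex = std::exp(arg);
      // both +/-alpha families combined (they share I4 in this projection)
      double g1 = 2.0 * k1 * E * ex;
      double g2 = 2.0 * k1 * ex * (1.0 + 2.0 * k2 * E * E);
      double b = (1.0 - 3.0 * kappa) * ca2;
      double H[3] = {kappa + b * tref[0] * tref[0],
                     kappa + b * tref[1] * tref[1],
                     b * tref[0] * tref[1]};
      ps.S[0] += 2.0 * g1 * H[0];
      ps.S[1] += 2.0 * g1 * H[1];
      ps.S[2] += 2.0 * g1 * H[2];
      for (int i = 0; i < 3; i++) for (int j = 0; j < 3; j++)
        ps.CC[i][j] += 4.0 * g2 * H[i] * H[j];
      ps.energy += (k1 / k2) * (ex - 1.0);
    }
  }

  if (parts & 2) {
    double a1 = Kvol * (J - 1.0) * J / 2.0;    // dPsi_v/dC = a1 * Cinv
    double a1p = Kvol * (2.0 * J - 1.0) / 2.0; // da1/dJ
    ps.S[0] += 2.0 * a1 * Ci[0];
    ps.S[1] += 2.0 * a1 * Ci[1];
    ps.S[2] += 2.0 * a1 * Ci[2];
    double cj = 4.0 * a1p * (J / 2.0), cm = -2.0 * a1;
    ps.CC[0][0] += cj * Ci[0] * Ci[0] + cm * 2.0 * Ci[0] * Ci[0];
    ps.CC[1][1] += cj * Ci[1] * Ci[1] + cm * 2.0 * Ci[1] * Ci[1];
    ps.CC[0][1] += cj * Ci[0] * Ci[1] + cm * 2.0 * Ci[2] * Ci[2];
    ps.CC[1][0] += cj * Ci[1] * Ci[0] + cm * 2.0 * Ci[2] * Ci[2];
    ps.CC[0][2] += cj * Ci[0] * Ci[2] + cm * 2.0 * Ci[0] * Ci[2];
    ps.CC[2][0] += cj * Ci[2] * Ci[0] + cm * 2.0 * Ci[0] * Ci[2];
    ps.CC[1][2] += cj * Ci[1] * Ci[2] + cm * 2.0 * Ci[1] * Ci[2];
    ps.CC[2][1] += cj * Ci[2] * Ci[1] + cm * 2.0 * Ci[1] * Ci[2];
    ps.CC[2][2] += cj * Ci[2] * Ci[2] + cm * (Ci[0] * Ci[1] + Ci[2] * Ci[2]);
    ps.energy += 0.5 * Kvol * (J - 1.0) * (J - 1.0);
  }
  return ps;
}

// expand Voigt CC (index pairs 11,22,12) into full CC_IJKL
static inline double CCfull(const double CC[3][3], int I, int J, int K, int L) {
  int a = (I == J) ? I : 2;
  int b = (K == L) ? K : 2;
  return CC[a][b];
}

// First-PK stress and dP/dF = d_ik S_JL + F_iM CC_MJPL F_kP
static inline void pk_and_tangent(const double F[2][2], const PointState& ps,
                                  double P[2][2], double A[2][2][2][2]) {
  double Sf[2][2] = {{ps.S[0], ps.S[2]}, {ps.S[2], ps.S[1]}};
  for (int i = 0; i < 2; i++) for (int J = 0; J < 2; J++)
    P[i][J] = F[i][0] * Sf[0][J] + F[i][1] * Sf[1][J];
  for (int i = 0; i < 2; i++) for (int J = 0; J < 2; J++)
    for (int k = 0; k < 2; k++) for (int L = 0; L < 2; L++) {
      double t = (i == k) ? Sf[J][L] : 0.0;
      for (int M = 0; M < 2; M++) for (int Pq = 0; Pq < 2; Pq++)
        t += F[i][M] * CCfull(ps.CC, M, J, Pq, L) * F[k][Pq];
      A[i][J][k][L] = t;
    }
}

// [[Rcpp::export]]
List ps_point_kernel(const arma::mat& F, double c10, double k1, double k2,
                     double kappa, double ca2, double sa2,
                     const arma::vec& tref, double Kvol) {
  double Ff[2][2] = {{F(0, 0), F(0, 1)}, {F(1, 0), F(1, 1)}};
  double tr[2] = {tref(0), tref(1)};
  double C[3] = {Ff[0][0] * Ff[0][0] + Ff[1][0] * Ff[1][0],
                 Ff[0][1] * Ff[0][1] + Ff[1][1] * Ff[1][1],
                 Ff[0][0] * Ff[0][1] + Ff[1][0] * Ff[1][1]};
  double J = Ff[0][0] * Ff[1][1] - Ff[0][1] * Ff[1][0];
  PointState ps = point_eval(C, J, c10, k1, k2, kappa, ca2, tr, Kvol, 3);
  if (!ps.ok) return List::create(Named("ok") = false);
  double P[2][2], A[2][2][2][2];
  pk_and_tangent(Ff, ps, P, A);
  double Sf[2][2] = {{ps.S[0], ps.S[2]}, {ps.S[2], ps.S[1]}};
  arma::mat sig(2, 2), Pm(2, 2), Sm(2, 2), tang(4, 4);
  for (int i = 0; i < 2; i++) for (int j = 0; j < 2; j++) {
    double t = 0;
    for (int M = 0; M < 2; M++) for (int N = 0; N < 2; N++)
      t += Ff[i][M] * Sf[M][N] * Ff[j][N];
    sig(i, j) = t / J;
    Pm(i, j) = P[i][j];
    Sm(i, j) = Sf[i][j];
  }
  for (int i = 0; i < 2; i++) for (int Jj = 0; Jj < 2; Jj++)
    for (int k = 0; k < 2; k++) for (int L = 0; L < 2; L++)
      tang(i + 2 * Jj, k + 2 * L) = A[i][Jj][k][L];
  return List::create(Named("ok") = true, Named("sigma") = sig,
                      Named("P") = Pm, Named("S") = Sm,
                      Named("tangent") = tang, Named("J") = ps.J,
                      Named("energy") = ps.energy);
}

// Assemble internal force, tangent triplets and diagnostics over all
// elements. nodes: n x 2 reference coords; elems: m x 4 (1-based, CCW);
// matp: m x 7 (c10, k1, k2, kappa, cos^2 a, sin^2 a, Kvol); tref: m x 2
// reference circumferential direction; u: 2n displacements.
// need_tangent = FALSE skips the stiffness triplets (residual-only pass
// for line-search trials).
// [[Rcpp::export]]
List asm_internal(const arma::mat& nodes, const arma::imat& elems,
                  const arma::mat& matp, const arma::mat& tref,
                  const arma::vec& u, bool need_tangent = true) {
  const int m = elems.n_rows;
  const double g = 1.0 / std::sqrt(3.0);
  const double gx[4] = {-g, g, g, -g};
  const double gy[4] = {-g, -g, g, g};

  // parent shape-function derivatives at the 5 quadrature points
  double dNall[5][4][2];
  for (int q = 0; q < 5; q++) {
    double xi = (q < 4) ? gx[q] : 0.0, eta = (q < 4) ? gy[q] : 0.0;
    double d[4][2] = {
      {-(1 - eta) / 4.0, -(1 - xi) / 4.0},
      { (1 - eta) / 4.0, -(1 + xi) / 4.0},
      { (1 + eta) / 4.0,  (1 + xi) / 4.0},
      {-(1 + eta) / 4.0,  (1 - xi) / 4.0}};
    for (int a = 0; a < 4; a++) { dNall[q][a][0] = d[a][0]; dNall[q][a][1] = d[a][1]; }
  }

  NumericVector fR(u.n_elem);
  double* f = REAL(fR);
  IntegerVector tiR(need_tangent ? m * 64 : 0), tjR(need_tangent ? m * 64 : 0);
  NumericVector tvR(need_tangent ? m * 64 : 0);
  int* ti = need_tangent ? INTEGER(tiR) : nullptr;
  int* tj = need_tangent ? INTEGER(tjR) : nullptr;
  double* tv = need_tangent ? REAL(tvR) : nullptr;
  double energy = 0.0, maxJdev = 0.0, minJ = 1e30;
  NumericMatrix sig_c(m, 3);
  NumericVector wels(m);

  long nt = 0;
  for (int e = 0; e < m; e++) {
    int nd[4];
    double X[4][2], U[4][2];
    for (int a = 0; a < 4; a++) {
      nd[a] = elems(e, a) - 1;
      X[a][0] = nodes(nd[a], 0); X[a][1] = nodes(nd[a], 1);
      U[a][0] = u(2 * nd[a]);    U[a][1] = u(2 * nd[a] + 1);
    }
    double tr[2] = {tref(e, 0), tref(e, 1)};
    double c10 = matp(e, 0), k1 = matp(e, 1), k2 = matp(e, 2),
      kap = matp(e, 3), ca2 = matp(e, 4), Kv = matp(e, 6);

    double ke[8][8];
    double fe[8] = {0, 0, 0, 0, 0, 0, 0, 0};
    if (need_tangent)
      for (int i = 0; i < 8; i++) for (int j = 0; j < 8; j++) ke[i][j] = 0.0;

    for (int q = 0; q < 5; q++) {
      double w = (q < 4) ? 1.0 : 4.0;
      int parts = (q < 4) ? 1 : 2;
      const double (*dN)[2] = dNall[q];
      double J0[2][2] = {{0, 0}, {0, 0}};
      for (int a = 0; a < 4; a++) {
        J0[0][0] += X[a][0] * dN[a][0]; J0[0][1] += X[a][0] * dN[a][1];
        J0[1][0] += X[a][1] * dN[a][0]; J0[1][1] += X[a][1] * dN[a][1];
      }
      double detJ0 = J0[0][0] * J0[1][1] - J0[0][1] * J0[1][0];
      if (detJ0 <= 0.0)
        return List::create(Named("ok") = false, Named("bad_elem") = e + 1,
                            Named("why") = "degenerate reference element");
      double id0 = 1.0 / detJ0;
      double G[4][2];
      for (int a = 0; a < 4; a++) {
        G[a][0] = ( J0[1][1] * dN[a][0] - J0[1][0] * dN[a][1]) * id0;
        G[a][1] = (-J0[0][1] * dN[a][0] + J0[0][0] * dN[a][1]) * id0;
      }
      double F[2][2] = {{1, 0}, {0, 1}};
      for (int a = 0; a < 4; a++) {
        F[0][0] += U[a][0] * G[a][0]; F[0][1] += U[a][0] * G[a][1];
        F[1][0] += U[a][1] * G[a][0]; F[1][1] += U[a][1] * G[a][1];
      }
      double C[3] = {F[0][0] * F[0][0] + F[1][0] * F[1][0],
                     F[0][1] * F[0][1] + F[1][1] * F[1][1],
                     F[0][0] * F[0][1] + F[1][0] * F[1][1]};
      double Jd = F[0][0] * F[1][1] - F[0][1] * F[1][0];
      PointState st = point_eval(C, Jd, c10, k1, k2, kap, ca2, tr, Kv, parts);
      if (!st.ok)
        return List::create(Named("ok") = false, Named("bad_elem") = e + 1,
                            Named("why") = (st.J <= 0.0) ?
                            "inverted element" : "fiber exponent overflow");
      // the volumetric constraint is enforced at the centroid point;
      // corner points carry the linear bending variation of J
      if (q == 4) {
        double dJ = std::fabs(st.J - 1.0);
        if (dJ > maxJdev) maxJdev = dJ;
      }
      if (st.J < minJ) minJ = st.J;
      double wd = w * detJ0;
      energy += wd * st.energy;
      double Sf[2][2] = {{st.S[0], st.S[2]}, {st.S[2], st.S[1]}};
      double P[2][2];
      for (int i = 0; i < 2; i++) for (int J = 0; J < 2; J++)
        P[i][J] = F[i][0] * Sf[0][J] + F[i][1] * Sf[1][J];
      for (int a = 0; a < 4; a++) {
        fe[2 * a]     += wd * (P[0][0] * G[a][0] + P[0][1] * G[a][1]);
        fe[2 * a + 1] += wd * (P[1][0] * G[a][0] + P[1][1] * G[a][1]);
      }
      if (need_tangent) {
        double A[2][2][2][2];
        pk_and_tangent(F, st, P, A);
        double AG[2][2][4][2]; // A contracted with G over L
        for (int i = 0; i < 2; i++) for (int J = 0; J < 2; J++)
          for (int b = 0; b < 4; b++) for (int k = 0; k < 2; k++)
            AG[i][J][b][k] = A[i][J][k][0] * G[b][0] + A[i][J][k][1] * G[b][1];
        for (int a = 0; a < 4; a++)
          for (int i = 0; i < 2; i++)
            for (int b = 0; b < 4; b++) for (int k = 0; k < 2; k++)
              ke[2 * a + i][2 * b + k] +=
                wd * (G[a][0] * AG[i][0][b][k] + G[a][1] * AG[i][1][b][k]);
      }
      if (q == 4) {
        PointState sf = point_eval(C, Jd, c10, k1, k2, kap, ca2, tr, Kv, 3);
        if (sf.ok) {
          double S2[2][2] = {{sf.S[0], sf.S[2]}, {sf.S[2], sf.S[1]}};
          double sg[2][2];
          for (int i = 0; i < 2; i++) for (int j = 0; j < 2; j++) {
            double t = 0;
            for (int M = 0; M < 2; M++) for (int N = 0; N < 2; N++)
              t += F[i][M] * S2[M][N] * F[j][N];
            sg[i][j] = t / sf.J;
          }
          sig_c(e, 0) = sg[0][0]; sig_c(e, 1) = sg[1][1]; sig_c(e, 2) = sg[0][1];
        }
        wels[e] = wd;
      }
    }

    for (int a = 0; a < 4; a++) for (int i = 0; i < 2; i++) {
      f[2 * nd[a] + i] += fe[2 * a + i];
      if (need_tangent)
        for (int b = 0; b < 4; b++) for (int k = 0; k < 2; k++) {
          ti[nt] = 2 * nd[a] + i + 1;
          tj[nt] = 2 * nd[b] + k + 1;
          tv[nt] = ke[2 * a + i][2 * b + k];
          nt++;
        }
    }
  }

  return List::create(Named("ok") = true, Named("f") = fR,
                      Named("i") = tiR, Named("j") = tjR, Named("v") = tvR,
                      Named("energy") = energy, Named("maxJdev") = maxJdev,
                      Named("minJ") = minJ, Named("bad_elem") = 0,
                      Named("sigma_centroid") = sig_c,
                      Named("elem_area") = wels);
}
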