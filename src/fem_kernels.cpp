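// Element kernels for the triquadratic (27-node) hexahedral Neo-Hookean
// wall solver: internal force, consistent tangent (material + initial-stress
// terms), strain energy, and the follower pressure load on 9-node quadratic
// luminal faces. Total Lagrangian formulation with respect to the measured
// geometry; an initial Cauchy stress field (pre-stress) enters the residual
// as P0 = J * sigma0 * F^{-T}.
//
// Units are the caller's responsibility (the R layer passes SI).
// Local node ordering is lexicographic: index = i + 3*j + 9*k with i the
// fastest-running (circumferential) direction; 1D nodes sit at -1, 0, 1.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double GP[3] = {-0.7745966692414834, 0.0, 0.7745966692414834};
static const double GW[3] = {0.5555555555555556, 0.8888888888888888,
                             0.5555555555555556};

static inline void shape1d(double x, double* N, double* dN) {
  N[0] = 0.5 * x * (x - 1.0); dN[0] = x - 0.5;
  N[1] = 1.0 - x * x;         dN[1] = -2.0 * x;
  N[2] = 0.5 * x * (x + 1.0); dN[2] = x + 0.5;
}

static void shape27(double xi, double eta, double ze,
                    double* N, double dN[][3]) {
  double nx[3], dx[3], ny[3], dy[3], nz[3], dz[3];
  shape1d(xi, nx, dx); shape1d(eta, ny, dy); shape1d(ze, nz, dz);
  int a = 0;
  for (int k = 0; k < 3; ++k)
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i, ++a) {
        N[a] = nx[i] * ny[j] * nz[k];
        dN[a][0] = dx[i] * ny[j] * nz[k];
        dN[a][1] = nx[i] * dy[j] * nz[k];
        dN[a][2] = nx[i] * ny[j] * dz[k];
      }
}

static inline double inv3(const double A[3][3], double Ai[3][3]) {
  double d = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
           - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
           + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  double id = 1.0 / d;
  Ai[0][0] =  (A[1][1] * A[2][2] - A[1][2] * A[2][1]) * id;
  Ai[0][1] = -(A[0][1] * A[2][2] - A[0][2] * A[2][1]) * id;
  Ai[0][2] =  (A[0][1] * A[1][2] - A[0][2] * A[1][1]) * id;
  Ai[1][0] = -(A[1][0] * A[2][2] - A[1][2] * A[2][0]) * id;
  Ai[1][1] =  (A[0][0] * A[2][2] - A[0][2] * A[2][0]) * id;
  Ai[1][2] = -(A[0][0] * A[1][2] - A[0][2] * A[1][0]) * id;
  Ai[2][0] =  (A[1][0] * A[2][1] - A[1][1] * A[2][0]) * id;
  Ai[2][1] = -(A[0][0] * A[2][1] - A[0][1] * A[2][0]) * id;
  Ai[2][2] =  (A[0][0] * A[1][1] - A[0][1] * A[1][0]) * id;
  return d;
}

// [[Rcpp::export(name = ".fem_assemble")]]
List fem_assemble(NumericMatrix X, IntegerMatrix conn, NumericMatrix U,
                  double G, double kappa,
                  Nullable<NumericMatrix> sigma0_ = R_NilValue,
                  bool want_tangent = false, bool want_stress = false) {
  const int nel = conn.nrow();
  const int nn = X.nrow();
  NumericVector fint(3 * nn);
  double energy = 0.0, jac_min = R_PosInf, detF_min = R_PosInf;
  bool has_s0 = sigma0_.isNotNull();
  NumericMatrix sigma0;
  if (has_s0) sigma0 = NumericMatrix(sigma0_);
  NumericMatrix stress_out;
  if (want_stress) stress_out = NumericMatrix(nel * 27, 6);

  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    ti.reserve((size_t)nel * 81 * 81);
    tj.reserve((size_t)nel * 81 * 81);
    tx.reserve((size_t)nel * 81 * 81);
  }

  double N[27], dN[27][3];
  double Xe[27][3], Ue[27][3];
  double gx[27][3];            // shape gradients w.r.t. X
  double pvec[27][3], svec[27][3];
  double Ke[81][81];

  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < 27; ++a) {
      int n = conn(e, a) - 1;
      Xe[a][0] = X(n, 0); Xe[a][1] = X(n, 1); Xe[a][2] = X(n, 2);
      Ue[a][0] = U(n, 0); Ue[a][1] = U(n, 1); Ue[a][2] = U(n, 2);
    }
    if (want_tangent)
      for (int p = 0; p < 81; ++p)
        for (int q = 0; q < 81; ++q) Ke[p][q] = 0.0;

    int qp = 0;
    for (int kq = 0; kq < 3; ++kq)
      for (int jq = 0; jq < 3; ++jq)
        for (int iq = 0; iq < 3; ++iq, ++qp) {
          shape27(GP[iq], GP[jq], GP[kq], N, dN);
          double w = GW[iq] * GW[jq] * GW[kq];
          double Jm[3][3] = {{0}}, Jmi[3][3];
          for (int a = 0; a < 27; ++a)
            for (int i = 0; i < 3; ++i)
              for (int A = 0; A < 3; ++A) Jm[i][A] += Xe[a][i] * dN[a][A];
          double detJ = inv3(Jm, Jmi);
          if (detJ < jac_min) jac_min = detJ;
          if (detJ <= 0) continue;  // reported via jac_min
          double wd = w * detJ;
          for (int a = 0; a < 27; ++a)
            for (int i = 0; i < 3; ++i)
              gx[a][i] = dN[a][0] * Jmi[0][i] + dN[a][1] * Jmi[1][i] +
                         dN[a][2] * Jmi[2][i];

          double F[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
          for (int a = 0; a < 27; ++a)
            for (int i = 0; i < 3; ++i)
              for (int J = 0; J < 3; ++J) F[i][J] += Ue[a][i] * gx[a][J];
          double Fi[3][3];
          double JF = inv3(F, Fi);
          if (JF < detF_min) detF_min = JF;
          if (JF <= 0) continue;
          double lnJ = std::log(JF);
          double FiT[3][3];
          for (int i = 0; i < 3; ++i)
            for (int J = 0; J < 3; ++J) FiT[i][J] = Fi[J][i];

          // first Piola-Kirchhoff stress
          double P[3][3];
          for (int i = 0; i < 3; ++i)
            for (int J = 0; J < 3; ++J)
              P[i][J] = G * (F[i][J] - FiT[i][J]) + kappa * lnJ * FiT[i][J];

          double S0[3][3] = {{0}}, S0FT[3][3] = {{0}};
          if (has_s0) {
            int row = e * 27 + qp;
            S0[0][0] = sigma0(row, 0); S0[1][1] = sigma0(row, 1);
            S0[2][2] = sigma0(row, 2);
            S0[0][1] = S0[1][0] = sigma0(row, 3);
            S0[1][2] = S0[2][1] = sigma0(row, 4);
            S0[0][2] = S0[2][0] = sigma0(row, 5);
            for (int i = 0; i < 3; ++i)
              for (int J = 0; J < 3; ++J) {
                double s = 0;
                for (int m = 0; m < 3; ++m) s += S0[i][m] * FiT[m][J];
                S0FT[i][J] = s;
                P[i][J] += JF * s;
              }
          }

          double I1 = F[0][0]*F[0][0] + F[0][1]*F[0][1] + F[0][2]*F[0][2]
                    + F[1][0]*F[1][0] + F[1][1]*F[1][1] + F[1][2]*F[1][2]
                    + F[2][0]*F[2][0] + F[2][1]*F[2][1] + F[2][2]*F[2][2];
          energy += (0.5 * G * (I1 - 3.0) - G * lnJ +
                     0.5 * kappa * lnJ * lnJ) * wd;

          for (int a = 0; a < 27; ++a) {
            int n = conn(e, a) - 1;
            for (int i = 0; i < 3; ++i)
              fint[3 * n + i] += (P[i][0] * gx[a][0] + P[i][1] * gx[a][1] +
                                  P[i][2] * gx[a][2]) * wd;
          }

          if (want_stress) {
            // total Cauchy stress: hyperelastic part + carried initial stress
            double B[3][3] = {{0}};
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j)
                for (int J = 0; J < 3; ++J) B[i][j] += F[i][J] * F[j][J];
            int row = e * 27 + qp;
            double c = G / JF, v = kappa * lnJ / JF;
            stress_out(row, 0) = c * (B[0][0] - 1.0) + v + S0[0][0];
            stress_out(row, 1) = c * (B[1][1] - 1.0) + v + S0[1][1];
            stress_out(row, 2) = c * (B[2][2] - 1.0) + v + S0[2][2];
            stress_out(row, 3) = c * B[0][1] + S0[0][1];
            stress_out(row, 4) = c * B[1][2] + S0[1][2];
            stress_out(row, 5) = c * B[0][2] + S0[0][2];
          }

          if (want_tangent) {
            double c2 = G - kappa * lnJ;
            for (int a = 0; a < 27; ++a)
              for (int i = 0; i < 3; ++i) {
                pvec[a][i] = FiT[i][0] * gx[a][0] + FiT[i][1] * gx[a][1] +
                             FiT[i][2] * gx[a][2];
                svec[a][i] = S0FT[i][0] * gx[a][0] + S0FT[i][1] * gx[a][1] +
                             S0FT[i][2] * gx[a][2];
              }
            for (int a = 0; a < 27; ++a) {
              for (int b = 0; b < 27; ++b) {
                double gg = gx[a][0] * gx[b][0] + gx[a][1] * gx[b][1] +
                            gx[a][2] * gx[b][2];
                for (int i = 0; i < 3; ++i) {
                  for (int k = 0; k < 3; ++k) {
                    double v = c2 * pvec[b][i] * pvec[a][k] +
                               kappa * pvec[a][i] * pvec[b][k];
                    if (i == k) v += G * gg;
                    if (has_s0)
                      v += JF * (svec[a][i] * pvec[b][k] -
                                 svec[b][i] * pvec[a][k]);
                    Ke[3 * a + i][3 * b + k] += v * wd;
                  }
                }
              }
            }
          }
        }

    if (want_tangent) {
      for (int a = 0; a < 27; ++a) {
        int na = conn(e, a) - 1;
        for (int b = 0; b < 27; ++b) {
          int nb = conn(e, b) - 1;
          for (int i = 0; i < 3; ++i)
            for (int k = 0; k < 3; ++k) {
              ti.push_back(3 * na + i + 1);
              tj.push_back(3 * nb + k + 1);
              tx.push_back(Ke[3 * a + i][3 * b + k]);
            }
        }
      }
    }
  }

  List out = List::create(_["fint"] = fint, _["energy"] = energy,
                          _["jac_min"] = jac_min, _["detF_min"] = detF_min);
  if (want_stress) out["stress"] = stress_out;
  if (want_tangent) {
    out["ti"] = IntegerVector(ti.begin(), ti.end());
    out["tj"] = IntegerVector(tj.begin(), tj.end());
    out["tx"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}

static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

// [[Rcpp::export(name = ".fem_follower_load")]]
List fem_follower_load(NumericMatrix X, NumericMatrix U,
                       IntegerMatrix faces, NumericVector pressure,
                       bool want_tangent = false) {
  const int nf = faces.nrow();
  NumericVector f(3 * X.nrow());
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    ti.reserve((size_t)nf * 729);
    tj.reserve((size_t)nf * 729);
    tx.reserve((size_t)nf * 729);
  }
  double n1[3], d1[3], n2[3], d2[3];
  double Ke[27][27];
  for (int e = 0; e < nf; ++e) {
    double xe[9][3];
    for (int a = 0; a < 9; ++a) {
      int n = faces(e, a) - 1;
      for (int i = 0; i < 3; ++i) xe[a][i] = X(n, i) + U(n, i);
    }
    double p = pressure[e];
    if (want_tangent)
      for (int q = 0; q < 27; ++q)
        for (int r = 0; r < 27; ++r) Ke[q][r] = 0.0;
    for (int jq = 0; jq < 3; ++jq) {
      shape1d(GP[jq], n2, d2);
      for (int iq = 0; iq < 3; ++iq) {
        shape1d(GP[iq], n1, d1);
        double w = GW[iq] * GW[jq];
        double N[9], Dxi[9], Deta[9];
        for (int j = 0; j < 3; ++j)
          for (int i = 0; i < 3; ++i) {
            N[i + 3 * j] = n1[i] * n2[j];
            Dxi[i + 3 * j] = d1[i] * n2[j];
            Deta[i + 3 * j] = n1[i] * d2[j];
          }
        double txi[3] = {0, 0, 0}, teta[3] = {0, 0, 0};
        for (int a = 0; a < 9; ++a)
          for (int i = 0; i < 3; ++i) {
            txi[i] += Dxi[a] * xe[a][i];
            teta[i] += Deta[a] * xe[a][i];
          }
        double nrm[3];
        cross3(txi, teta, nrm);
        for (int a = 0; a < 9; ++a) {
          int n = faces(e, a) - 1;
          for (int i = 0; i < 3; ++i)
            f[3 * n + i] += p * N[a] * nrm[i] * w;
        }
        if (want_tangent) {
          // d(x_xi x x_eta) under du_b = e_k: dN_b/dxi (e_k x x_eta)
          //                               + dN_b/deta (x_xi x e_k)
          double ek[3], c1[3], c2[3];
          for (int k = 0; k < 3; ++k) {
            ek[0] = ek[1] = ek[2] = 0.0; ek[k] = 1.0;
            cross3(ek, teta, c1);
            cross3(txi, ek, c2);
            for (int b = 0; b < 9; ++b) {
              double g1 = Dxi[b], g2 = Deta[b];
              for (int a = 0; a < 9; ++a) {
                double paw = p * N[a] * w;
                for (int i = 0; i < 3; ++i)
                  Ke[3 * a + i][3 * b + k] += paw * (g1 * c1[i] + g2 * c2[i]);
              }
            }
          }
        }
      }
    }
    if (want_tangent) {
      for (int a = 0; a < 9; ++a) {
        int na = faces(e, a) - 1;
        for (int b = 0; b < 9; ++b) {
          int nb = faces(e, b) - 1;
          for (int i = 0; i < 3; ++i)
            for (int k = 0; k < 3; ++k) {
              ti.push_back(3 * na + i + 1);
              tj.push_back(3 * nb + k + 1);
              tx.push_back(Ke[3 * a + i][3 * b + k]);
            }
        }
      }
    }
  }
  List out = List::create(_["f"] = f);
  if (want_tangent) {
    out["ti"] = IntegerVector(ti.begin(), ti.end());
    out["tj"] = IntegerVector(tj.begin(), tj.end());
    out["tx"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}
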