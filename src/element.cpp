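// Hexahedral element kernel for the quasi-static LV solver.
// Total-Lagrangian trilinear brick with selective reduced integration:
// the Guccione deviatoric response and the active fiber stress are
// integrated at 2x2x2 Gauss points, the volumetric penalty at the
// element centre (mitigating locking under near-incompressibility).
// Units: mm, kPa, mN.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Mat3 {
  double m[3][3];
  Mat3() { for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) m[i][j] = 0.0; }
};

const double SG[8][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1, 1}, {1, -1, 1}, {1, 1, 1}, {-1, 1, 1}};

void shape_grad(double xi, double eta, double zeta, double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    dN[a][0] = SG[a][0] * (1 + SG[a][1] * eta) * (1 + SG[a][2] * zeta) / 8.0;
    dN[a][1] = SG[a][1] * (1 + SG[a][0] * xi) * (1 + SG[a][2] * zeta) / 8.0;
    dN[a][2] = SG[a][2] * (1 + SG[a][0] * xi) * (1 + SG[a][1] * eta) / 8.0;
  }
}

double det3(const Mat3& A) {
  return A.m[0][0] * (A.m[1][1] * A.m[2][2] - A.m[1][2] * A.m[2][1]) -
         A.m[0][1] * (A.m[1][0] * A.m[2][2] - A.m[1][2] * A.m[2][0]) +
         A.m[0][2] * (A.m[1][0] * A.m[2][1] - A.m[1][1] * A.m[2][0]);
}

Mat3 inv3(const Mat3& A, double& det) {
  det = det3(A);
  Mat3 B;
  B.m[0][0] = (A.m[1][1] * A.m[2][2] - A.m[1][2] * A.m[2][1]) / det;
  B.m[0][1] = (A.m[0][2] * A.m[2][1] - A.m[0][1] * A.m[2][2]) / det;
  B.m[0][2] = (A.m[0][1] * A.m[1][2] - A.m[0][2] * A.m[1][1]) / det;
  B.m[1][0] = (A.m[1][2] * A.m[2][0] - A.m[1][0] * A.m[2][2]) / det;
  B.m[1][1] = (A.m[0][0] * A.m[2][2] - A.m[0][2] * A.m[2][0]) / det;
  B.m[1][2] = (A.m[0][2] * A.m[1][0] - A.m[0][0] * A.m[1][2]) / det;
  B.m[2][0] = (A.m[1][0] * A.m[2][1] - A.m[1][1] * A.m[2][0]) / det;
  B.m[2][1] = (A.m[0][1] * A.m[2][0] - A.m[0][0] * A.m[2][1]) / det;
  B.m[2][2] = (A.m[0][0] * A.m[1][1] - A.m[0][1] * A.m[1][0]) / det;
  return B;
}

// second Piola-Kirchhoff stress in GLOBAL coordinates at one point
// mat = (C, bf, bt, bfs, kappa, Tact_kPa, cross_frac)
// vol_term: include the kappa penalty (centre point only)
// dev_term: include the Guccione + active parts (full quadrature)
Mat3 pk2_stress(const Mat3& F, const double* Rf, const double* mat,
                bool dev_term, bool vol_term) {
  // E = (F^T F - I)/2, then rotate to fiber coords Ef = R^T E R
  Mat3 Cg, E;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += F.m[k][i] * F.m[k][j];
      Cg.m[i][j] = s;
      E.m[i][j] = (s - (i == j ? 1.0 : 0.0)) / 2.0;
    }
  Mat3 Sf;
  double J = det3(F);
  if (J <= 0) stop("element inversion: det(F) <= 0");
  if (dev_term) {
    Mat3 Ef;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k)
          for (int l = 0; l < 3; ++l)
            s += Rf[k + 3 * i] * E.m[k][l] * Rf[l + 3 * j];
        Ef.m[i][j] = s;
      }
    double Q = mat[1] * Ef.m[0][0] * Ef.m[0][0] +
      mat[2] * (Ef.m[1][1] * Ef.m[1][1] + Ef.m[2][2] * Ef.m[2][2] +
                Ef.m[1][2] * Ef.m[1][2] + Ef.m[2][1] * Ef.m[2][1]) +
      mat[3] * (Ef.m[0][1] * Ef.m[0][1] + Ef.m[1][0] * Ef.m[1][0] +
                Ef.m[0][2] * Ef.m[0][2] + Ef.m[2][0] * Ef.m[2][0]);
    double CeQ = mat[0] * std::exp(Q);
    double B[3][3] = {{mat[1], mat[3], mat[3]},
                      {mat[3], mat[2], mat[2]},
                      {mat[3], mat[2], mat[2]}};
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Sf.m[i][j] = CeQ * B[i][j] * Ef.m[i][j];
    // active Cauchy stress T f^ x f^ (+ cross-fiber fractions) pulled
    // back:  S_act = J T (d0 x d0) / lambda_d^2 per direction
    double Tact = mat[5];
    if (Tact != 0.0) {
      double cf[3] = {1.0, mat[6], mat[6]};
      for (int d = 0; d < 3; ++d) {
        // lambda^2 = d0 . C d0 with d0 the d-th fiber-frame axis
        double lam2 = 0;
        for (int k = 0; k < 3; ++k)
          for (int l = 0; l < 3; ++l)
            lam2 += Rf[k + 3 * d] * Cg.m[k][l] * Rf[l + 3 * d];
        Sf.m[d][d] += J * Tact * cf[d] / lam2;
      }
    }
  }
  // rotate back: S = R Sf R^T
  Mat3 S;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k)
        for (int l = 0; l < 3; ++l)
          s += Rf[i + 3 * k] * Sf.m[k][l] * Rf[j + 3 * l];
      S.m[i][j] = s;
    }
  if (vol_term) {
    double det;
    Mat3 Cinv = inv3(Cg, det);
    double kap = mat[4];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        S.m[i][j] += kap * (J - 1.0) * J * Cinv.m[i][j];
  }
  return S;
}

void element_force(const double* X, const double* u, const double* Rf,
                   const double* mat, double* f) {
  for (int i = 0; i < 24; ++i) f[i] = 0.0;
  const double g = 1.0 / std::sqrt(3.0);
  double dN[8][3], dNdX[8][3];
  // pass 1: deviatoric + active at 8 Gauss points
  // pass 2: volumetric at the centre with weight 8
  for (int pass = 0; pass < 2; ++pass) {
    int npts = pass == 0 ? 8 : 1;
    for (int q = 0; q < npts; ++q) {
      double xi = pass == 0 ? g * SG[q][0] : 0.0;
      double eta = pass == 0 ? g * SG[q][1] : 0.0;
      double zeta = pass == 0 ? g * SG[q][2] : 0.0;
      double w = pass == 0 ? 1.0 : 8.0;
      shape_grad(xi, eta, zeta, dN);
      Mat3 J0;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int a = 0; a < 8; ++a) s += X[a + 8 * i] * dN[a][j];
          J0.m[i][j] = s;
        }
      double detJ;
      Mat3 J0inv = inv3(J0, detJ);
      if (detJ <= 0) stop("element has non-positive reference Jacobian");
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double s = 0;
          for (int j = 0; j < 3; ++j) s += dN[a][j] * J0inv.m[j][i];
          dNdX[a][i] = s;
        }
      Mat3 F;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = (i == j) ? 1.0 : 0.0;
          for (int a = 0; a < 8; ++a) s += u[a + 8 * i] * dNdX[a][j];
          F.m[i][j] = s;
        }
      Mat3 S = pk2_stress(F, Rf, mat, pass == 0, pass == 1);
      // P = F S ; f_a += P dN_a detJ w
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double s = 0;
          for (int j = 0; j < 3; ++j) {
            double P = 0;
            for (int k = 0; k < 3; ++k) P += F.m[i][k] * S.m[k][j];
            s += P * dNdX[a][j];
          }
          f[a + 8 * i] += s * detJ * w;
        }
    }
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector hex_force_cpp(NumericMatrix X, NumericMatrix u,
                            NumericMatrix Rf, NumericVector mat) {
  NumericVector f(24);
  element_force(X.begin(), u.begin(), Rf.begin(), mat.begin(), f.begin());
  return f;
}

// internal force and numerically differentiated consistent tangent
// [[Rcpp::export]]
List hex_force_tangent_cpp(NumericMatrix X, NumericMatrix u,
                           NumericMatrix Rf, NumericVector mat,
                           double h = 1e-7) {
  NumericVector f(24);
  element_force(X.begin(), u.begin(), Rf.begin(), mat.begin(), f.begin());
  NumericMatrix K(24, 24);
  std::vector<double> up(u.begin(), u.end()), fp(24);
  for (int d = 0; d < 24; ++d) {
    double keep = up[d];
    up[d] = keep + h;
    element_force(X.begin(), up.data(), Rf.begin(), mat.begin(), fp.data());
    up[d] = keep;
    for (int i = 0; i < 24; ++i) K(i, d) = (fp[i] - f[i]) / h;
  }
  return List::create(_["f"] = f, _["K"] = K);
}

// batched assembly: forces and tangents for all elements at once
// Xs, us: 8 x 3 x ne (flattened column-major as 24*ne), Rfs: 9*ne,
// mats: 7*ne. Returns total force entries and dense per-element blocks.
// [[Rcpp::export]]
List assemble_elements_cpp(NumericVector Xs, NumericVector us,
                           NumericVector Rfs, NumericVector mats,
                           int ne, bool tangent, double h = 1e-7) {
  NumericMatrix Fmat(24, ne);
  NumericVector Ks(tangent ? 576 * ne : 0);
  std::vector<double> up(24), fp(24), f0(24);
  for (int e = 0; e < ne; ++e) {
    const double* X = &Xs[24 * e];
    const double* u = &us[24 * e];
    const double* Rf = &Rfs[9 * e];
    const double* mat = &mats[7 * e];
    element_force(X, u, Rf, mat, f0.data());
    for (int i = 0; i < 24; ++i) Fmat(i, e) = f0[i];
    if (tangent) {
      for (int i = 0; i < 24; ++i) up[i] = u[i];
      for (int d = 0; d < 24; ++d) {
        double keep = up[d];
        up[d] = keep + h;
        element_force(X, up.data(), Rf, mat, fp.data());
        up[d] = keep;
        for (int i = 0; i < 24; ++i)
          Ks[576 * e + i + 24 * d] = (fp[i] - f0[i]) / h;
      }
    }
  }
  return List::create(_["f"] = Fmat, _["K"] = Ks);
}

// deformation gradient at element centres for all elements
// [[Rcpp::export]]
NumericVector centre_def_grad_cpp(NumericVector Xs, NumericVector us, int ne) {
  NumericVector out(9 * ne);
  double dN[8][3], dNdX[8][3];
  shape_grad(0.0, 0.0, 0.0, dN);
  for (int e = 0; e < ne; ++e) {
    const double* X = &Xs[24 * e];
    const double* u = &us[24 * e];
    Mat3 J0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int a = 0; a < 8; ++a) s += X[a + 8 * i] * dN[a][j];
        J0.m[i][j] = s;
      }
    double detJ;
    Mat3 J0inv = inv3(J0, detJ);
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) {
        double s = 0;
        for (int j = 0; j < 3; ++j) s += dN[a][j] * J0inv.m[j][i];
        dNdX[a][i] = s;
      }
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = (i == j) ? 1.0 : 0.0;
        for (int a = 0; a < 8; ++a) s += u[a + 8 * i] * dNdX[a][j];
        out[9 * e + i + 3 * j] = s;
      }
  }
  return out;
}
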