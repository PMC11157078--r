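// Axisymmetric large-deformation FE core: uncoupled first-order Ogden
// material evaluated in principal stretches, and residual/tangent assembly
// for 8-node serendipity quadrilaterals (full 2*pi weighting).
//
// Units: mm, N, MPa (c and kappa are passed in MPa).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// ---- Ogden material in principal stretches -------------------------------
// Psi = (c/m^2) * sum(lt_i^m - 1) + (kappa/2) * ln(J)^2, lt_i = J^(-1/3) l_i
//
// tau_i   : principal Kirchhoff stresses
// gam(i,j): d tau_i / d ln(l_j)
struct OgdenPoint {
  double tau[3];
  double gam[3][3];
  double psi;
};

OgdenPoint ogden_point(const double lam[3], double c, double m, double kappa) {
  OgdenPoint r;
  double J = lam[0] * lam[1] * lam[2];
  double lnJ = std::log(J);
  double Jm13 = std::pow(J, -1.0 / 3.0);
  double lt[3], lm[3];
  double s = 0.0;
  for (int i = 0; i < 3; ++i) {
    lt[i] = Jm13 * lam[i];
    lm[i] = std::pow(lt[i], m);
    s += lm[i];
  }
  for (int i = 0; i < 3; ++i)
    r.tau[i] = (c / m) * (lm[i] - s / 3.0) + kappa * lnJ;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double dij = (i == j) ? 1.0 : 0.0;
      r.gam[i][j] = c * (lm[i] * (dij - 1.0 / 3.0) - lm[j] / 3.0 + s / 9.0)
        + kappa;
    }
  r.psi = (c / (m * m)) * (s - 3.0) + 0.5 * kappa * lnJ * lnJ;
  return r;
}

// ---- Q8 serendipity shape functions --------------------------------------
// local node order: (-1,-1) (1,-1) (1,1) (-1,1) (0,-1) (1,0) (0,1) (-1,0)
void q8_shape(double xi, double eta, double N[8], double dN[8][2]) {
  const double xs[8] = {-1, 1, 1, -1, 0, 1, 0, -1};
  const double es[8] = {-1, -1, 1, 1, -1, 0, 1, 0};
  for (int a = 0; a < 8; ++a) {
    double xa = xs[a], ea = es[a];
    if (xa != 0.0 && ea != 0.0) {          // corner
      N[a] = 0.25 * (1 + xi * xa) * (1 + eta * ea) * (xi * xa + eta * ea - 1);
      dN[a][0] = 0.25 * xa * (1 + eta * ea) * (2 * xi * xa + eta * ea);
      dN[a][1] = 0.25 * ea * (1 + xi * xa) * (xi * xa + 2 * eta * ea);
    } else if (xa == 0.0) {                // midside on xi
      N[a] = 0.5 * (1 - xi * xi) * (1 + eta * ea);
      dN[a][0] = -xi * (1 + eta * ea);
      dN[a][1] = 0.5 * ea * (1 - xi * xi);
    } else {                               // midside on eta
      N[a] = 0.5 * (1 + xi * xa) * (1 - eta * eta);
      dN[a][0] = 0.5 * xa * (1 - eta * eta);
      dN[a][1] = -eta * (1 + xi * xa);
    }
  }
}

void gauss_rule(int n, double pts[3], double wts[3]) {
  if (n == 2) {
    pts[0] = -1.0 / std::sqrt(3.0); pts[1] = 1.0 / std::sqrt(3.0);
    wts[0] = 1.0; wts[1] = 1.0;
  } else {
    pts[0] = -std::sqrt(0.6); pts[1] = 0.0; pts[2] = std::sqrt(0.6);
    wts[0] = 5.0 / 9.0; wts[1] = 8.0 / 9.0; wts[2] = 5.0 / 9.0;
  }
}

}  // namespace

// Cauchy stress, strain energy density and Kirchhoff principal stresses for
// an arbitrary deformation gradient (material-point evaluation for tests
// and calibration).
// [[Rcpp::export]]
List ogden_stress_cpp(const arma::mat& F, double c, double m, double kappa) {
  double J = arma::det(F);
  if (J <= 0) stop("det(F) <= 0");
  arma::mat b = F * F.t();
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, b);
  double lam[3];
  for (int i = 0; i < 3; ++i) lam[i] = std::sqrt(std::max(eval(i), 1e-300));
  OgdenPoint op = ogden_point(lam, c, m, kappa);
  arma::mat sigma(3, 3, arma::fill::zeros);
  for (int i = 0; i < 3; ++i)
    sigma += (op.tau[i] / J) * (evec.col(i) * evec.col(i).t());
  return List::create(
    _["sigma"] = sigma,
    _["tau"] = NumericVector::create(op.tau[0], op.tau[1], op.tau[2]),
    _["psi"] = op.psi,
    _["J"] = J);
}

// Assemble internal force, tangent triplets, total strain energy and
// volume-ratio statistics for the axisymmetric Q8 mesh.
//
// X    : n x 2 reference coordinates (R, Z)
// u    : n x 2 nodal displacements (u_r, u_z)
// conn : nel x 8 connectivity, 0-based
// [[Rcpp::export]]
List fem_assemble_cpp(const arma::mat& X, const arma::mat& u,
                      const arma::imat& conn, double c, double m,
                      double kappa, int ngauss = 3) {
  const int nel = conn.n_rows;
  const int nnode = X.n_rows;
  const int ndof = 2 * nnode;
  const double two_pi = 2.0 * M_PI;

  double gp[3], gw[3];
  gauss_rule(ngauss, gp, gw);

  arma::vec fint(ndof, arma::fill::zeros);
  const int per_el = 16 * 16;
  std::vector<int> Ki(nel * per_el), Kj(nel * per_el);
  std::vector<double> Kx(nel * per_el);
  double energy = 0.0;
  double max_abs_jm1 = 0.0;
  bool ok = true;

  double N[8], dNxi[8][2];

  for (int e = 0; e < nel && ok; ++e) {
    arma::mat::fixed<8, 2> Xe, ue, xe;
    int dofmap[16];
    for (int a = 0; a < 8; ++a) {
      int n = conn(e, a);
      Xe(a, 0) = X(n, 0); Xe(a, 1) = X(n, 1);
      ue(a, 0) = u(n, 0); ue(a, 1) = u(n, 1);
      xe(a, 0) = Xe(a, 0) + ue(a, 0);
      xe(a, 1) = Xe(a, 1) + ue(a, 1);
      dofmap[2 * a] = 2 * n;
      dofmap[2 * a + 1] = 2 * n + 1;
    }
    arma::mat::fixed<16, 16> Ke;
    Ke.zeros();
    arma::vec::fixed<16> fe;
    fe.zeros();

    for (int ig = 0; ig < ngauss && ok; ++ig) {
      for (int jg = 0; jg < ngauss && ok; ++jg) {
        q8_shape(gp[ig], gp[jg], N, dNxi);
        // reference and current Jacobians
        double Jr[2][2] = {{0, 0}, {0, 0}}, Jc[2][2] = {{0, 0}, {0, 0}};
        double Rg = 0.0, rg = 0.0;
        for (int a = 0; a < 8; ++a) {
          for (int i = 0; i < 2; ++i) {
            Jr[i][0] += dNxi[a][i] * Xe(a, 0);
            Jr[i][1] += dNxi[a][i] * Xe(a, 1);
            Jc[i][0] += dNxi[a][i] * xe(a, 0);
            Jc[i][1] += dNxi[a][i] * xe(a, 1);
          }
          Rg += N[a] * Xe(a, 0);
          rg += N[a] * xe(a, 0);
        }
        double detJr = Jr[0][0] * Jr[1][1] - Jr[0][1] * Jr[1][0];
        double detJc = Jc[0][0] * Jc[1][1] - Jc[0][1] * Jc[1][0];
        if (detJr <= 0 || detJc <= 0 || rg <= 0 || Rg <= 0) { ok = false; break; }
        // dN/dX and dN/dx
        double dNX[8][2], dNx[8][2];
        double iJr[2][2] = {{ Jr[1][1] / detJr, -Jr[0][1] / detJr},
                            {-Jr[1][0] / detJr,  Jr[0][0] / detJr}};
        double iJc[2][2] = {{ Jc[1][1] / detJc, -Jc[0][1] / detJc},
                            {-Jc[1][0] / detJc,  Jc[0][0] / detJc}};
        for (int a = 0; a < 8; ++a) {
          dNX[a][0] = iJr[0][0] * dNxi[a][0] + iJr[0][1] * dNxi[a][1];
          dNX[a][1] = iJr[1][0] * dNxi[a][0] + iJr[1][1] * dNxi[a][1];
          dNx[a][0] = iJc[0][0] * dNxi[a][0] + iJc[0][1] * dNxi[a][1];
          dNx[a][1] = iJc[1][0] * dNxi[a][0] + iJc[1][1] * dNxi[a][1];
        }
        // deformation gradient: in-plane F2 and hoop stretch r/R
        double F2[2][2] = {{1, 0}, {0, 1}};
        for (int a = 0; a < 8; ++a) {
          F2[0][0] += ue(a, 0) * dNX[a][0];
          F2[0][1] += ue(a, 0) * dNX[a][1];
          F2[1][0] += ue(a, 1) * dNX[a][0];
          F2[1][1] += ue(a, 1) * dNX[a][1];
        }
        double lam3 = rg / Rg;
        double detF2 = F2[0][0] * F2[1][1] - F2[0][1] * F2[1][0];
        if (detF2 <= 0 || lam3 <= 0) { ok = false; break; }
        // in-plane principal stretches and directions from b = F2 F2^T
        double b11 = F2[0][0] * F2[0][0] + F2[0][1] * F2[0][1];
        double b22 = F2[1][0] * F2[1][0] + F2[1][1] * F2[1][1];
        double b12 = F2[0][0] * F2[1][0] + F2[0][1] * F2[1][1];
        double tr2 = 0.5 * (b11 + b22);
        double disc = std::sqrt(std::max(0.25 * (b11 - b22) * (b11 - b22)
                                         + b12 * b12, 0.0));
        double e1 = tr2 + disc, e2 = std::max(tr2 - disc, 1e-300);
        double n1[2], n2[2];
        if (disc < 1e-12 * std::max(1.0, e1)) {
          n1[0] = 1; n1[1] = 0; n2[0] = 0; n2[1] = 1;
        } else {
          double v1 = b12, v2 = e1 - b11;
          double w1 = e1 - b22, w2 = b12;
          if (v1 * v1 + v2 * v2 < w1 * w1 + w2 * w2) { v1 = w1; v2 = w2; }
          double nv = std::sqrt(v1 * v1 + v2 * v2);
          n1[0] = v1 / nv; n1[1] = v2 / nv;
          n2[0] = -n1[1]; n2[1] = n1[0];
        }
        double lam[3] = {std::sqrt(e1), std::sqrt(e2), lam3};
        double J = detF2 * lam3;
        OgdenPoint op = ogden_point(lam, c, m, kappa);
        max_abs_jm1 = std::max(max_abs_jm1, std::fabs(J - 1.0));

        // Cauchy stress
        double s11 = (op.tau[0] / J) * n1[0] * n1[0]
                   + (op.tau[1] / J) * n2[0] * n2[0];
        double s22 = (op.tau[0] / J) * n1[1] * n1[1]
                   + (op.tau[1] / J) * n2[1] * n2[1];
        double s12 = (op.tau[0] / J) * n1[0] * n1[1]
                   + (op.tau[1] / J) * n2[0] * n2[1];
        double s33 = op.tau[2] / J;

        // spatial tangent, Voigt (rr, zz, rz, tt), Cauchy scale
        double ciijj[3][3], cshear;
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            ciijj[i][j] = (op.gam[i][j]
                           - 2.0 * op.tau[i] * ((i == j) ? 1.0 : 0.0)) / J;
        if (std::fabs(e1 - e2) > 1e-9 * std::max(1.0, std::max(e1, e2)))
          cshear = (op.tau[0] * e2 - op.tau[1] * e1) / (e1 - e2) / J;
        else
          cshear = (0.5 * (op.gam[0][0] - op.gam[0][1]) - op.tau[0]) / J;

        // in-plane 4th-order tensor in the r-z frame
        double ct[2][2][2][2];
        const double* nn[2] = {n1, n2};
        for (int i = 0; i < 2; ++i)
          for (int j = 0; j < 2; ++j)
            for (int k = 0; k < 2; ++k)
              for (int l = 0; l < 2; ++l) {
                double v = 0.0;
                for (int a = 0; a < 2; ++a)
                  for (int b = 0; b < 2; ++b) {
                    v += ciijj[a][b] * nn[a][i] * nn[a][j]
                                     * nn[b][k] * nn[b][l];
                    if (a != b)
                      v += cshear * (nn[a][i] * nn[b][j] * nn[a][k] * nn[b][l]
                                   + nn[a][i] * nn[b][j] * nn[b][k] * nn[a][l]);
                  }
                ct[i][j][k][l] = v;
              }
        const int vi[3] = {0, 1, 0}, vj[3] = {1, 1, 0};
        // Voigt index map: 0 -> (0,0) rr, 1 -> (1,1) zz, 2 -> (0,1) rz
        const int pi_[3] = {0, 1, 0}, pj_[3] = {0, 1, 1};
        (void)vi; (void)vj;
        double D[4][4];
        for (int A = 0; A < 3; ++A)
          for (int B = 0; B < 3; ++B)
            D[A][B] = ct[pi_[A]][pj_[A]][pi_[B]][pj_[B]];
        // hoop couplings: c_{aa33} rotated onto in-plane Voigt components
        double V1[3] = {n1[0] * n1[0], n1[1] * n1[1], n1[0] * n1[1]};
        double V2[3] = {n2[0] * n2[0], n2[1] * n2[1], n2[0] * n2[1]};
        for (int A = 0; A < 3; ++A) {
          D[A][3] = ciijj[0][2] * V1[A] + ciijj[1][2] * V2[A];
          D[3][A] = ciijj[2][0] * V1[A] + ciijj[2][1] * V2[A];
        }
        D[3][3] = ciijj[2][2];

        double dv = two_pi * rg * detJc * gw[ig] * gw[jg];
        double dV0 = two_pi * Rg * detJr * gw[ig] * gw[jg];
        energy += op.psi * dV0;

        // B matrix (4 x 16)
        double B[4][16];
        for (int a = 0; a < 8; ++a) {
          B[0][2 * a] = dNx[a][0]; B[0][2 * a + 1] = 0.0;
          B[1][2 * a] = 0.0;       B[1][2 * a + 1] = dNx[a][1];
          B[2][2 * a] = dNx[a][1]; B[2][2 * a + 1] = dNx[a][0];
          B[3][2 * a] = N[a] / rg; B[3][2 * a + 1] = 0.0;
        }
        double svec[4] = {s11, s22, s12, s33};
        for (int p = 0; p < 16; ++p) {
          double fp = 0.0;
          for (int A = 0; A < 4; ++A) fp += B[A][p] * svec[A];
          fe(p) += fp * dv;
        }
        // material part: B^T D B
        double DB[4][16];
        for (int A = 0; A < 4; ++A)
          for (int p = 0; p < 16; ++p) {
            double v = 0.0;
            for (int Bc = 0; Bc < 4; ++Bc) v += D[A][Bc] * B[Bc][p];
            DB[A][p] = v;
          }
        for (int p = 0; p < 16; ++p)
          for (int q = 0; q < 16; ++q) {
            double v = 0.0;
            for (int A = 0; A < 4; ++A) v += B[A][p] * DB[A][q];
            Ke(p, q) += v * dv;
          }
        // geometric part
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b) {
            double g =
              dNx[a][0] * (s11 * dNx[b][0] + s12 * dNx[b][1]) +
              dNx[a][1] * (s12 * dNx[b][0] + s22 * dNx[b][1]);
            double gh = s33 * N[a] * N[b] / (rg * rg);
            Ke(2 * a, 2 * b) += (g + gh) * dv;
            Ke(2 * a + 1, 2 * b + 1) += g * dv;
          }
      }
    }
    if (!ok) break;
    for (int p = 0; p < 16; ++p) {
      fint(dofmap[p]) += fe(p);
      for (int q = 0; q < 16; ++q) {
        int idx = e * per_el + 16 * p + q;
        Ki[idx] = dofmap[p] + 1;  // 1-based for Matrix::sparseMatrix
        Kj[idx] = dofmap[q] + 1;
        Kx[idx] = Ke(p, q);
      }
    }
  }

  return List::create(
    _["ok"] = ok,
    _["fint"] = fint,
    _["Ki"] = IntegerVector(Ki.begin(), Ki.end()),
    _["Kj"] = IntegerVector(Kj.begin(), Kj.end()),
    _["Kx"] = NumericVector(Kx.begin(), Kx.end()),
    _["energy"] = energy,
    _["max_abs_jm1"] = max_abs_jm1);
}

// Accumulate triplet values into a fixed CSC x-slot via a precomputed map.
// [[Rcpp::export]]
NumericVector accum_pattern_cpp(const NumericVector& x,
                                const IntegerVector& map, int nnz) {
  NumericVector out(nnz);
  for (int k = 0; k < x.size(); ++k) out[map[k] - 1] += x[k];
  return out;
}
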