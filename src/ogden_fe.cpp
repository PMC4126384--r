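// Element kernels for the total-Lagrangian hyperelastic solver:
// one-term Ogden (decoupled isochoric/volumetric) stress via spectral
// decomposition, 8-node hexahedra with 2x2x2 Gauss quadrature, and a
// consistent element tangent by central finite differencing of the analytic
// first Piola stress (symmetrized; the exact tangent is symmetric).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

const double GPT = 0.5773502691896258; // 1/sqrt(3)

// local corner signs, VTK hexahedron ordering
const double XI[8]  = {-1,  1,  1, -1, -1,  1,  1, -1};
const double ETA[8] = {-1, -1,  1,  1, -1, -1,  1,  1};
const double ZET[8] = {-1, -1, -1, -1,  1,  1,  1,  1};

void shape_grad(double xi, double eta, double zet, mat &dN) {
  for (int a = 0; a < 8; ++a) {
    dN(a, 0) = 0.125 * XI[a] * (1.0 + eta * ETA[a]) * (1.0 + zet * ZET[a]);
    dN(a, 1) = 0.125 * (1.0 + xi * XI[a]) * ETA[a] * (1.0 + zet * ZET[a]);
    dN(a, 2) = 0.125 * (1.0 + xi * XI[a]) * (1.0 + eta * ETA[a]) * ZET[a];
  }
}

// Cyclic-Jacobi eigendecomposition of a symmetric 3x3 matrix; fast,
// branch-light and robust at (near-)degenerate eigenvalues.
void jacobi_eig3(const mat &Ain, vec &ev, mat &V) {
  double A[3][3] = {{Ain(0,0), Ain(0,1), Ain(0,2)},
                    {Ain(1,0), Ain(1,1), Ain(1,2)},
                    {Ain(2,0), Ain(2,1), Ain(2,2)}};
  double Q[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
  for (int sweep = 0; sweep < 24; ++sweep) {
    double off = std::abs(A[0][1]) + std::abs(A[0][2]) + std::abs(A[1][2]);
    if (off < 1e-15 * (std::abs(A[0][0]) + std::abs(A[1][1]) +
                       std::abs(A[2][2]) + 1e-300))
      break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (A[p][q] == 0.0) continue;
        double theta = (A[q][q] - A[p][p]) / (2.0 * A[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::abs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; ++k) {
          double akp = A[k][p], akq = A[k][q];
          A[k][p] = c * akp - s * akq;
          A[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = A[p][k], aqk = A[q][k];
          A[p][k] = c * apk - s * aqk;
          A[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double qkp = Q[k][p], qkq = Q[k][q];
          Q[k][p] = c * qkp - s * qkq;
          Q[k][q] = s * qkp + c * qkq;
        }
      }
  }
  ev.set_size(3);
  V.set_size(3, 3);
  for (int i = 0; i < 3; ++i) {
    ev(i) = A[i][i];
    for (int k = 0; k < 3; ++k) V(k, i) = Q[k][i];
  }
}

// Second Piola-Kirchhoff stress of the decoupled one-term Ogden law.
// W = (2 mu / alpha^2) (lb1^a + lb2^a + lb3^a - 3) + (kappa/2)(J-1)^2,
// lb_i = J^(-1/3) lambda_i.  Principal Kirchhoff stresses:
// tau_i = (2 mu / alpha)(lb_i^a - mean(lb^a)) + kappa J (J - 1).
bool ogden_spk(const mat &F, double mu, double alpha, double kappa,
               mat &S, double &J) {
  J = det(F);
  if (!(J > 0.0)) return false;
  mat C = F.t() * F;
  vec ev;
  mat V;
  jacobi_eig3(C, ev, V);
  ev = clamp(ev, 1e-12, datum::inf);
  double Jm13 = std::pow(J, -1.0 / 3.0);
  vec lba(3);
  for (int i = 0; i < 3; ++i)
    lba(i) = std::pow(Jm13 * std::sqrt(ev(i)), alpha);
  double mn = accu(lba) / 3.0;
  double pvol = kappa * J * (J - 1.0);
  S.zeros(3, 3);
  for (int i = 0; i < 3; ++i) {
    double tau = (2.0 * mu / alpha) * (lba(i) - mn) + pvol;
    S += (tau / ev(i)) * (V.col(i) * V.col(i).t());
  }
  return true;
}

bool ogden_pk1_(const mat &F, double mu, double alpha, double kappa,
                mat &P, double &J) {
  mat S;
  if (!ogden_spk(F, mu, alpha, kappa, S, J)) return false;
  P = F * S;
  return true;
}

// strain-energy density at F
bool ogden_W(const mat &F, double mu, double alpha, double kappa,
             double &W) {
  double J = det(F);
  if (!(J > 0.0)) return false;
  mat C = F.t() * F;
  vec ev;
  mat V;
  jacobi_eig3(C, ev, V);
  ev = clamp(ev, 1e-12, datum::inf);
  double Jm13 = std::pow(J, -1.0 / 3.0);
  double s = 0.0;
  for (int i = 0; i < 3; ++i)
    s += std::pow(Jm13 * std::sqrt(ev(i)), alpha);
  W = (2.0 * mu / (alpha * alpha)) * (s - 3.0) +
      0.5 * kappa * (J - 1.0) * (J - 1.0);
  return true;
}

} // namespace

// [[Rcpp::export]]
arma::mat cpp_ogden_pk1(const arma::mat &F, double mu, double alpha,
                        double kappa) {
  mat P;
  double J;
  if (!ogden_pk1_(F, mu, alpha, kappa, P, J))
    Rcpp::stop("deformation gradient has non-positive determinant");
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_ogden_cauchy(const arma::mat &F, double mu, double alpha,
                           double kappa) {
  mat P;
  double J;
  if (!ogden_pk1_(F, mu, alpha, kappa, P, J))
    Rcpp::stop("deformation gradient has non-positive determinant");
  return (P * F.t()) / J;
}

// Assemble internal forces (and optionally the consistent tangent as
// triplets) for all hexahedral elements.  `u` is the global displacement
// vector with dof = 3*(node-1)+component, `conn` is 1-based.
// [[Rcpp::export]]
Rcpp::List cpp_hex_assemble(const arma::mat &nodes, const arma::imat &conn,
                            const arma::vec &u, double mu, double alpha,
                            double kappa, bool want_tangent,
                            double fd_h = 1e-6) {
  const int nel = conn.n_rows;
  const int nn = nodes.n_rows;
  vec r(3 * nn, fill::zeros);
  std::vector<double> Tv;
  std::vector<int> Ti, Tj;
  if (want_tangent) {
    Tv.reserve((size_t)nel * 576);
    Ti.reserve((size_t)nel * 576);
    Tj.reserve((size_t)nel * 576);
  }
  double minJ = datum::inf;
  double energy = 0.0;
  int bad = 0;

  mat dN(8, 3), Xe(8, 3), ue(8, 3);
  ivec ids(8);

  for (int e = 0; e < nel && bad == 0; ++e) {
    for (int a = 0; a < 8; ++a) {
      int nid = conn(e, a) - 1;
      ids(a) = nid;
      Xe.row(a) = nodes.row(nid);
      for (int c = 0; c < 3; ++c) ue(a, c) = u(3 * nid + c);
    }
    mat fe(8, 3, fill::zeros);
    mat Ke;
    if (want_tangent) Ke.zeros(24, 24);

    for (int g = 0; g < 8; ++g) {
      shape_grad(GPT * XI[g], GPT * ETA[g], GPT * ZET[g], dN);
      mat J0 = Xe.t() * dN;
      double detJ0 = det(J0);
      mat dNdX = dN * inv(J0);
      mat F = eye(3, 3) + ue.t() * dNdX;
      mat P;
      double J;
      if (!ogden_pk1_(F, mu, alpha, kappa, P, J)) { bad = e + 1; break; }
      if (J < minJ) minJ = J;
      double Wgp;
      ogden_W(F, mu, alpha, kappa, Wgp);
      energy += Wgp * detJ0;
      fe += dNdX * P.t() * detJ0;

      if (want_tangent) {
        mat A(9, 9);
        bool ok = true;
        for (int n = 0; n < 9 && ok; ++n) {
          mat Fp = F, Fm = F, Pp, Pm;
          double Jp, Jm;
          Fp(n % 3, n / 3) += fd_h;
          Fm(n % 3, n / 3) -= fd_h;
          ok = ogden_pk1_(Fp, mu, alpha, kappa, Pp, Jp) &&
               ogden_pk1_(Fm, mu, alpha, kappa, Pm, Jm);
          if (ok) A.col(n) = vectorise((Pp - Pm) / (2.0 * fd_h));
        }
        if (!ok) { bad = e + 1; break; }
        mat B(9, 24, fill::zeros);
        for (int b = 0; b < 8; ++b)
          for (int k = 0; k < 3; ++k)
            for (int i = 0; i < 3; ++i)
              B(i + 3 * k, 3 * b + i) = dNdX(b, k);
        Ke += detJ0 * (B.t() * A * B);
      }
    }
    if (bad) break;

    for (int a = 0; a < 8; ++a)
      for (int c = 0; c < 3; ++c)
        r(3 * ids(a) + c) += fe(a, c);

    if (want_tangent) {
      Ke = 0.5 * (Ke + Ke.t());
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          int gi = 3 * ids(a) + i + 1;
          for (int b = 0; b < 8; ++b)
            for (int j = 0; j < 3; ++j) {
              Ti.push_back(gi);
              Tj.push_back(3 * ids(b) + j + 1);
              Tv.push_back(Ke(3 * a + i, 3 * b + j));
            }
        }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("r") = r,
      Rcpp::Named("i") = Rcpp::wrap(Ti),
      Rcpp::Named("j") = Rcpp::wrap(Tj),
      Rcpp::Named("v") = Rcpp::wrap(Tv),
      Rcpp::Named("min_detF") = minJ,
      Rcpp::Named("energy") = energy,
      Rcpp::Named("bad_element") = bad);
}

// Element-averaged Cauchy stress (rows: xx, yy, zz, xy, yz, xz) and
// element-averaged first Piola stress component P33, for post-processing.
// [[Rcpp::export]]
Rcpp::List cpp_hex_stress(const arma::mat &nodes, const arma::imat &conn,
                          const arma::vec &u, double mu, double alpha,
                          double kappa) {
  const int nel = conn.n_rows;
  mat sig(nel, 6, fill::zeros);
  vec p33(nel, fill::zeros);
  mat dN(8, 3), Xe(8, 3), ue(8, 3);

  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < 8; ++a) {
      int nid = conn(e, a) - 1;
      Xe.row(a) = nodes.row(nid);
      for (int c = 0; c < 3; ++c) ue(a, c) = u(3 * nid + c);
    }
    mat sacc(3, 3, fill::zeros);
    double pacc = 0.0;
    for (int g = 0; g < 8; ++g) {
      shape_grad(GPT * XI[g], GPT * ETA[g], GPT * ZET[g], dN);
      mat J0 = Xe.t() * dN;
      mat dNdX = dN * inv(J0);
      mat F = eye(3, 3) + ue.t() * dNdX;
      mat P;
      double J;
      if (!ogden_pk1_(F, mu, alpha, kappa, P, J))
        Rcpp::stop("element %d inverted during stress recovery", e + 1);
      sacc += (P * F.t()) / J;
      pacc += P(2, 2);
    }
    sacc /= 8.0;
    sig(e, 0) = sacc(0, 0);
    sig(e, 1) = sacc(1, 1);
    sig(e, 2) = sacc(2, 2);
    sig(e, 3) = sacc(0, 1);
    sig(e, 4) = sacc(1, 2);
    sig(e, 5) = sacc(0, 2);
    p33(e) = pacc / 8.0;
  }
  return Rcpp::List::create(Rcpp::Named("cauchy") = sig,
                            Rcpp::Named("P33") = p33);
}
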