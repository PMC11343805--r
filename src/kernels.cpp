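// Finite element kernels for the coupled mechano-chemo-biological artery model.
//
// All quantities are SI.  Concentration degrees of freedom are carried in
// scaled form (nutrients / 1e-5 kg/m^3, cells / 1e13 cells/m^3); Gauss-point
// internal variables are stored in physical units.
//
// Element dof layout (trilinear hex, 8 nodes, 6 dof/node):
//   [ux, uy, uz, C_N^, C_Mo^, C_Ma^] per node, node-major.
// Gauss-point internal variable layout (7 per point):
//   [C_F, C_SMC, rho0_c, lambda_r^1 .. lambda_r^4]   (physical units)
//
// The element residual is evaluated a large number of times per assembly
// (finite-difference tangent), so the inner loops use raw fixed-size
// arrays (row-major 3x3) rather than dynamically allocated matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

struct Pars {
  double mu, k1, k2, kappa, kr, lpre, alpha, rc, Kc, rsmc;
  double EMoMa, EMaF, aMo, rho0m, rho0c_bar, Csmc_bar, rho_tilde;
  double DNmin, DNmax, DMo, DMa, rMo, rMa, RN, rho00;
  double scaleN, scaleC, kcmN, kcmMo, kcmMa;
  int nF;
  double phi[8];
};

Pars unpack_pars(const arma::vec& q) {
  Pars P;
  P.mu = q(0);  P.k1 = q(1);  P.k2 = q(2);  P.kappa = q(3);  P.kr = q(4);
  P.lpre = q(5); P.alpha = q(6); P.rc = q(7); P.Kc = q(8); P.rsmc = q(9);
  P.EMoMa = q(10); P.EMaF = q(11); P.aMo = q(12); P.rho0m = q(13);
  P.rho0c_bar = q(14); P.Csmc_bar = q(15); P.rho_tilde = q(16);
  P.DNmin = q(17); P.DNmax = q(18); P.DMo = q(19); P.DMa = q(20);
  P.rMo = q(21); P.rMa = q(22); P.RN = q(23); P.rho00 = q(24);
  P.scaleN = q(25); P.scaleC = q(26);
  P.kcmN = q(27); P.kcmMo = q(28); P.kcmMa = q(29);
  P.nF = (int) q(30);
  if (P.nF > 8) Rcpp::stop("at most 8 fiber families supported");
  for (int j = 0; j < P.nF; ++j) P.phi[j] = q(31 + j);
  return P;
}

const double SGN[8][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1, 1}, {1, -1, 1}, {1, 1, 1}, {-1, 1, 1}};
const double GLOC = 0.5773502691896258;  // 1/sqrt(3)

inline double det3(const double* m) {
  return m[0] * (m[4] * m[8] - m[5] * m[7]) -
         m[1] * (m[3] * m[8] - m[5] * m[6]) +
         m[2] * (m[3] * m[7] - m[4] * m[6]);
}

// inverse of a row-major 3x3; returns its determinant
inline double inv3(const double* m, double* out) {
  const double d = det3(m);
  const double id = 1.0 / d;
  out[0] = (m[4] * m[8] - m[5] * m[7]) * id;
  out[1] = (m[2] * m[7] - m[1] * m[8]) * id;
  out[2] = (m[1] * m[5] - m[2] * m[4]) * id;
  out[3] = (m[5] * m[6] - m[3] * m[8]) * id;
  out[4] = (m[0] * m[8] - m[2] * m[6]) * id;
  out[5] = (m[2] * m[3] - m[0] * m[5]) * id;
  out[6] = (m[3] * m[7] - m[4] * m[6]) * id;
  out[7] = (m[1] * m[6] - m[0] * m[7]) * id;
  out[8] = (m[0] * m[4] - m[1] * m[3]) * id;
  return d;
}

void shape_hex(double xi, double eta, double ze, double* N, double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    const double sx = SGN[a][0], sy = SGN[a][1], sz = SGN[a][2];
    N[a] = 0.125 * (1 + sx * xi) * (1 + sy * eta) * (1 + sz * ze);
    dN[a][0] = 0.125 * sx * (1 + sy * eta) * (1 + sz * ze);
    dN[a][1] = 0.125 * (1 + sx * xi) * sy * (1 + sz * ze);
    dN[a][2] = 0.125 * (1 + sx * xi) * (1 + sy * eta) * sz;
  }
}

// Backward-Euler update of the remodeling stretch: scalar Newton on
//   x - lr_n - dt * kr * (lam_tot/x - lpre)/(lpre - 1) = 0
inline double lambda_r_update(double lr_n, double lam_tot, double dt,
                              double kr, double lpre) {
  double x = lr_n;
  for (int it = 0; it < 50; ++it) {
    const double f = x - lr_n - dt * kr * (lam_tot / x - lpre) / (lpre - 1.0);
    const double fp = 1.0 + dt * kr * lam_tot / (x * x * (lpre - 1.0));
    const double dx = -f / fp;
    x += dx;
    if (std::fabs(dx) < 1e-14 * std::max(1.0, std::fabs(x))) break;
  }
  return x;
}

// Backward-Euler update of all Gauss-point internal variables.
// hn, hout: length-7 arrays; C row-major; fib points at nF*3 doubles.
void update_h_core(const double* hn, const double* C, const double* fib,
                   double CMa_new, double dt, const Pars& P, double* hout) {
  const double CF = hn[0] + dt * P.EMaF * CMa_new;
  const double CS = hn[1] + dt * P.rsmc * CF;
  const double cap = P.Kc * P.rho0c_bar;
  const double s = P.rc * (CS - P.Csmc_bar);
  double rho = hn[2];
  const double denom = 1.0 + dt * s / cap;
  if (hn[2] < cap && denom > 0.0) {
    // implicit linear solve of rho = rho_n + dt*s*(1 - rho/cap); branch
    // consistency follows from sign(rho - cap) = sign(rho_n - cap)
    const double cand = (hn[2] + dt * s) / denom;
    if (cand <= cap) rho = cand;
  }
  hout[0] = CF;
  hout[1] = CS;
  hout[2] = rho;
  for (int j = 0; j < P.nF; ++j) {
    const double* a = fib + 3 * j;
    double aCa = 0;
    for (int i = 0; i < 3; ++i)
      for (int k = 0; k < 3; ++k) aCa += a[i] * C[i * 3 + k] * a[k];
    hout[3 + j] = lambda_r_update(hn[3 + j], std::sqrt(aCa), dt, P.kr,
                                  P.lpre);
  }
}

inline double plaque_frho(double ratio, double rho_tilde) {
  double fr = (rho_tilde - ratio) / (rho_tilde - 1.0);
  if (fr < 0.0) fr = 0.0;
  if (fr > 1.0) fr = 1.0;
  return fr;
}

// 1st Piola-Kirchhoff stress at fixed internal variables and element
// pressure.  F, C, FinvT, Pk row-major 3x3.
void pk1_core(const double* F, const double* C, double J,
              const double* FinvT, const double* h, const double* fib,
              double rho0, double p_el, const Pars& P, double* Pk) {
  const double I1 = C[0] + C[4] + C[8];
  const double cm = P.rho0m * P.mu * std::pow(J, -2.0 / 3.0);
  const double pj = rho0 * p_el * J;
  for (int k = 0; k < 9; ++k) {
    Pk[k] = cm * (2.0 * F[k] - (2.0 / 3.0) * I1 * FinvT[k]) + pj * FinvT[k];
  }
  for (int j = 0; j < P.nF; ++j) {
    const double lr = h[3 + j];
    const double* a = fib + 3 * j;
    double aCa = 0;
    for (int i = 0; i < 3; ++i)
      for (int k = 0; k < 3; ++k) aCa += a[i] * C[i * 3 + k] * a[k];
    const double I4e = aCa / (lr * lr);
    const double e = I4e - 1.0;
    if (e > 0.0) {
      const double coef = P.phi[j] * h[2] * P.k1 * e *
                          std::exp(P.k2 * e * e) * (2.0 / (lr * lr));
      double Fa[3];
      for (int i = 0; i < 3; ++i)
        Fa[i] = F[i * 3] * a[0] + F[i * 3 + 1] * a[1] + F[i * 3 + 2] * a[2];
      for (int i = 0; i < 3; ++i)
        for (int k = 0; k < 3; ++k) Pk[i * 3 + k] += coef * Fa[i] * a[k];
    }
  }
}

double energy_core(const double* F, const double* h, const double* fib,
                   double theta, double p, double CMo, double CMa,
                   const Pars& P) {
  double C[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += F[k * 3 + i] * F[k * 3 + j];
      C[i * 3 + j] = s;
    }
  const double J = det3(F);
  const double I1bar = std::pow(J, -2.0 / 3.0) * (C[0] + C[4] + C[8]);
  double W = P.rho0m * P.mu * (I1bar - 3.0);
  for (int j = 0; j < P.nF; ++j) {
    const double lr = h[3 + j];
    const double* a = fib + 3 * j;
    double aCa = 0;
    for (int i = 0; i < 3; ++i)
      for (int k = 0; k < 3; ++k) aCa += a[i] * C[i * 3 + k] * a[k];
    const double e = aCa / (lr * lr) - 1.0;
    if (e > 0.0)
      W += P.phi[j] * h[2] * P.k1 / (2.0 * P.k2) * std::expm1(P.k2 * e * e);
  }
  const double rho0 = P.rho0m + h[2] + P.alpha * (CMo + CMa + h[0] + h[1]);
  const double d = theta - rho0 / P.rho00;
  W += rho0 * (0.5 * P.kappa * d * d + p * (J - theta));
  return W;
}

struct GpCache {
  double dNdX[8][3];
  double N[8];
  double detJ0;
  double F[9];
  double cN, cMo, cMa, cMo_n, cMa_n;
  double gN[3], gMo[3], gMa[3];
  double rho0;
  double h[7];
};

// Element residual with internal-variable update and exact (p, theta)
// condensation.  Returns false on an inverted element.
// X: 8x3 reference coordinates, fib: 8 x (3 nF) fiber directions per GP,
// hn: 8x7 internal variables at t_n (all row-major raw arrays).
bool elem_core(const double X[8][3], const double* pe, const double* pe_n,
               const double hn[8][7], const double* fib, int fibstride,
               const Pars& P, double dt, double* R, double hnew[8][7],
               double& p_el, double& th_el) {
  GpCache gps[8];
  double N[8], dN[8][3];
  double Sth = 0, Sden = 0, Sg = 0;
  for (int k = 0; k < 48; ++k) R[k] = 0.0;
  for (int gp = 0; gp < 8; ++gp) {
    GpCache& g = gps[gp];
    shape_hex(SGN[gp][0] * GLOC, SGN[gp][1] * GLOC, SGN[gp][2] * GLOC, N, dN);
    double Jac[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int a = 0; a < 8; ++a) s += X[a][i] * dN[a][j];
        Jac[i * 3 + j] = s;
      }
    double Jinv[9];
    const double dj = inv3(Jac, Jinv);
    if (dj <= 0.0) return false;
    g.detJ0 = dj;
    for (int a = 0; a < 8; ++a) {
      for (int i = 0; i < 3; ++i) {
        g.dNdX[a][i] = dN[a][0] * Jinv[i] + dN[a][1] * Jinv[3 + i] +
                       dN[a][2] * Jinv[6 + i];
      }
      g.N[a] = N[a];
    }
    double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
    double vN = 0, vMo = 0, vMa = 0, vMo_n = 0, vMa_n = 0;
    double gN[3] = {0, 0, 0}, gMo[3] = {0, 0, 0}, gMa[3] = {0, 0, 0};
    for (int a = 0; a < 8; ++a) {
      const double* ua = pe + a * 6;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) F[i * 3 + j] += ua[i] * g.dNdX[a][j];
      vN += N[a] * ua[3];
      vMo += N[a] * ua[4];
      vMa += N[a] * ua[5];
      vMo_n += N[a] * pe_n[a * 6 + 4];
      vMa_n += N[a] * pe_n[a * 6 + 5];
      for (int i = 0; i < 3; ++i) {
        gN[i] += g.dNdX[a][i] * ua[3];
        gMo[i] += g.dNdX[a][i] * ua[4];
        gMa[i] += g.dNdX[a][i] * ua[5];
      }
    }
    const double Jd = det3(F);
    if (Jd <= 0.0) return false;
    for (int k = 0; k < 9; ++k) g.F[k] = F[k];
    g.cN = vN; g.cMo = vMo; g.cMa = vMa; g.cMo_n = vMo_n; g.cMa_n = vMa_n;
    for (int i = 0; i < 3; ++i) {
      g.gN[i] = gN[i]; g.gMo[i] = gMo[i]; g.gMa[i] = gMa[i];
    }
    double C[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += F[k * 3 + i] * F[k * 3 + j];
        C[i * 3 + j] = s;
      }
    update_h_core(hn[gp], C, fib + (size_t)gp * fibstride,
                  vMa * P.scaleC, dt, P, g.h);
    for (int k = 0; k < 7; ++k) hnew[gp][k] = g.h[k];
    g.rho0 = P.rho0m + g.h[2] +
             P.alpha * ((vMo + vMa) * P.scaleC + g.h[0] + g.h[1]);
    Sth += g.rho0 * Jd * dj;
    Sden += g.rho0 * dj;
    Sg += g.rho0 * (g.rho0 / P.rho00) * dj;
  }
  th_el = Sth / Sden;
  const double gbar = Sg / Sden;
  p_el = P.kappa * (th_el - gbar);

  const double RNhat = P.RN / P.scaleN;
  for (int gp = 0; gp < 8; ++gp) {
    const GpCache& g = gps[gp];
    const double dj = g.detJ0;
    double C[9], Finv[9], Ci[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += g.F[k * 3 + i] * g.F[k * 3 + j];
        C[i * 3 + j] = s;
      }
    const double Jd = inv3(g.F, Finv);
    inv3(C, Ci);
    double FinvT[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) FinvT[i * 3 + j] = Finv[j * 3 + i];
    double Pk[9];
    pk1_core(g.F, C, Jd, FinvT, g.h, fib + (size_t)gp * fibstride,
             g.rho0, p_el, P, Pk);
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        R[a * 6 + i] += (Pk[i * 3] * g.dNdX[a][0] +
                         Pk[i * 3 + 1] * g.dNdX[a][1] +
                         Pk[i * 3 + 2] * g.dNdX[a][2]) * dj;

    const double fr = plaque_frho(g.rho0 / P.rho00, P.rho_tilde);
    const double DN = (1.0 - fr) * P.DNmin + fr * P.DNmax;
    double CigN[3], CigMo[3], CigMa[3];
    for (int i = 0; i < 3; ++i) {
      CigN[i] = Ci[i * 3] * g.gN[0] + Ci[i * 3 + 1] * g.gN[1] +
                Ci[i * 3 + 2] * g.gN[2];
      CigMo[i] = Ci[i * 3] * g.gMo[0] + Ci[i * 3 + 1] * g.gMo[1] +
                 Ci[i * 3 + 2] * g.gMo[2];
      CigMa[i] = Ci[i * 3] * g.gMa[0] + Ci[i * 3 + 1] * g.gMa[1] +
                 Ci[i * 3 + 2] * g.gMa[2];
    }
    double AN[3], AMo[3], AMa[3];
    for (int i = 0; i < 3; ++i) {
      AN[i] = DN * Jd * CigN[i];
      AMo[i] = P.DMo * Jd * CigMo[i] - (P.rMo * P.scaleN) * g.cMo * CigN[i];
      AMa[i] = P.DMa * Jd * CigMa[i] - (P.rMa * P.scaleN) * g.cMa * CigN[i];
    }
    const double reacMo =
        (g.cMo - g.cMo_n) / dt + (P.EMoMa + P.aMo) * g.cMo;
    const double reacMa =
        (g.cMa - g.cMa_n) / dt - P.EMoMa * g.cMo + P.EMaF * g.cMa;
    for (int a = 0; a < 8; ++a) {
      const double* dNa = g.dNdX[a];
      R[a * 6 + 3] += P.kcmN *
          (dNa[0] * AN[0] + dNa[1] * AN[1] + dNa[2] * AN[2] +
           g.N[a] * RNhat) * dj;
      R[a * 6 + 4] += P.kcmMo *
          (g.N[a] * reacMo +
           dNa[0] * AMo[0] + dNa[1] * AMo[1] + dNa[2] * AMo[2]) * dj;
      R[a * 6 + 5] += P.kcmMa *
          (g.N[a] * reacMa +
           dNa[0] * AMa[0] + dNa[1] * AMa[1] + dNa[2] * AMa[2]) * dj;
    }
  }
  return true;
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_remodeling_tensor(double lr, const arma::vec& a) {
  if (lr <= 0) stop("remodeling stretch must be positive");
  arma::mat aa = a * a.t();
  return lr * aa + (1.0 / std::sqrt(lr)) * (arma::eye(3, 3) - aa);
}

// [[Rcpp::export]]
List cpp_elastic_measures(const arma::mat& F, const arma::vec& lr,
                          const arma::mat& A) {
  const double J = arma::det(F);
  if (J <= 0) stop("inverted state: det(F) <= 0");
  const arma::mat C = F.t() * F;
  const double I1bar = std::pow(J, -2.0 / 3.0) * arma::trace(C);
  const int nF = lr.n_elem;
  arma::vec I4e(nF), lam_e(nF), lam_tot(nF);
  for (int j = 0; j < nF; ++j) {
    const arma::vec3 a = A.row(j).t();
    const double aCa = arma::as_scalar(a.t() * C * a);
    lam_tot(j) = std::sqrt(aCa);
    I4e(j) = aCa / (lr(j) * lr(j));
    lam_e(j) = std::sqrt(I4e(j));
  }
  return List::create(_["J"] = J, _["I1bar"] = I1bar, _["I4e"] = I4e,
                      _["lambda_e"] = lam_e, _["lambda_total"] = lam_tot);
}

namespace {
// Row-major copies for the point-wise exported wrappers.
void to_raw(const arma::mat& M, double* out) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out[i * 3 + j] = M(i, j);
}
std::vector<double> fib_raw(const arma::mat& A) {
  std::vector<double> f(A.n_rows * 3);
  for (arma::uword j = 0; j < A.n_rows; ++j)
    for (int i = 0; i < 3; ++i) f[3 * j + i] = A(j, i);
  return f;
}
}  // namespace

// [[Rcpp::export]]
double cpp_energy_density(const arma::mat& F, const arma::vec& h,
                          const arma::mat& A, double theta, double p,
                          double CMo, double CMa, const arma::vec& par) {
  Pars P = unpack_pars(par);
  double Fr[9], hh[7];
  to_raw(F, Fr);
  for (int k = 0; k < 7; ++k) hh[k] = h(k);
  std::vector<double> fr = fib_raw(A);
  return energy_core(Fr, hh, fr.data(), theta, p, CMo, CMa, P);
}

// [[Rcpp::export]]
arma::mat cpp_pk1(const arma::mat& F, const arma::vec& h, const arma::mat& A,
                  double theta, double p, double CMo, double CMa,
                  const arma::vec& par) {
  (void)theta;  // P does not depend on theta at fixed (h, p)
  Pars P = unpack_pars(par);
  double Fr[9], hh[7];
  to_raw(F, Fr);
  for (int k = 0; k < 7; ++k) hh[k] = h(k);
  const double rho0 = P.rho0m + hh[2] + P.alpha * (CMo + CMa + hh[0] + hh[1]);
  double C[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += Fr[k * 3 + i] * Fr[k * 3 + j];
      C[i * 3 + j] = s;
    }
  double Finv[9], FinvT[9];
  const double J = inv3(Fr, Finv);
  if (J <= 0) stop("inverted state: det(F) <= 0");
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) FinvT[i * 3 + j] = Finv[j * 3 + i];
  std::vector<double> fr = fib_raw(A);
  double Pk[9];
  pk1_core(Fr, C, J, FinvT, hh, fr.data(), rho0, p, P, Pk);
  arma::mat out(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = Pk[i * 3 + j];
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_update_h(const arma::vec& h_n, const arma::mat& F,
                       const arma::mat& A, double CMa_new, double dt,
                       const arma::vec& par) {
  Pars P = unpack_pars(par);
  double hn[7], ho[7], Fr[9], C[9];
  for (int k = 0; k < 7; ++k) hn[k] = h_n(k);
  to_raw(F, Fr);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += Fr[k * 3 + i] * Fr[k * 3 + j];
      C[i * 3 + j] = s;
    }
  std::vector<double> fr = fib_raw(A);
  update_h_core(hn, C, fr.data(), CMa_new, dt, P, ho);
  arma::vec out(7);
  for (int k = 0; k < 7; ++k) out(k) = ho[k];
  return out;
}

// Assemble the global residual (and optionally element-FD tangent triplets)
// over all hex elements.  elems is 1-based.  fd_central selects central
// (two-sided) or forward differencing for the element tangent.
// [[Rcpp::export]]
List fem_assemble(const arma::mat& nodes, const arma::imat& elems,
                  const arma::vec& pvec, const arma::vec& pvec_n,
                  const arma::mat& h_n, const arma::mat& fib,
                  const arma::vec& par, double dt, bool want_tangent,
                  double fd_eps, bool fd_central) {
  const Pars P = unpack_pars(par);
  const int nel = elems.n_rows;
  const int nn = nodes.n_rows;
  const int ndof = 6 * nn;
  const int fibstride = fib.n_cols;
  arma::vec Rg(ndof, arma::fill::zeros);
  arma::mat hnew_out(h_n.n_rows, 7);
  arma::vec pel(nel), thel(nel);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    ti.reserve((size_t)nel * 1600);
    tj.reserve((size_t)nel * 1600);
    tx.reserve((size_t)nel * 1600);
  }
  bool ok = true;
  double X[8][3], hloc[8][7], hne[8][7], hdump[8][7];
  std::vector<double> floc(8 * fibstride);
  double pe[48], pen[48], Re[48], Rp[48], Rm[48];
  double Ke[48 * 48];
  int gdof[48];
  for (int e = 0; e < nel && ok; ++e) {
    for (int a = 0; a < 8; ++a) {
      const int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) X[a][i] = nodes(n, i);
      for (int c = 0; c < 6; ++c) {
        gdof[a * 6 + c] = n * 6 + c;
        pe[a * 6 + c] = pvec(n * 6 + c);
        pen[a * 6 + c] = pvec_n(n * 6 + c);
      }
    }
    for (int gp = 0; gp < 8; ++gp) {
      for (int k = 0; k < 7; ++k) hloc[gp][k] = h_n((size_t)e * 8 + gp, k);
      for (int c = 0; c < fibstride; ++c)
        floc[(size_t)gp * fibstride + c] = fib((size_t)e * 8 + gp, c);
    }
    double p_e, th_e;
    if (!elem_core(X, pe, pen, hloc, floc.data(), fibstride, P, dt, Re, hne,
                   p_e, th_e)) {
      ok = false;
      break;
    }
    for (int k = 0; k < 48; ++k) Rg(gdof[k]) += Re[k];
    for (int gp = 0; gp < 8; ++gp)
      for (int k = 0; k < 7; ++k) hnew_out((size_t)e * 8 + gp, k) = hne[gp][k];
    pel(e) = p_e;
    thel(e) = th_e;
    if (want_tangent) {
      double d1, d2;
      for (int k = 0; k < 48 && ok; ++k) {
        const double h0 = pe[k];
        const double step = fd_eps * (1.0 + std::fabs(h0));
        pe[k] = h0 + step;
        const bool o1 = elem_core(X, pe, pen, hloc, floc.data(), fibstride,
                                  P, dt, Rp, hdump, d1, d2);
        bool o2 = true;
        if (fd_central) {
          pe[k] = h0 - step;
          o2 = elem_core(X, pe, pen, hloc, floc.data(), fibstride, P, dt,
                         Rm, hdump, d1, d2);
        }
        pe[k] = h0;
        if (!o1 || !o2) { ok = false; break; }
        if (fd_central) {
          for (int r = 0; r < 48; ++r)
            Ke[r * 48 + k] = (Rp[r] - Rm[r]) / (2.0 * step);
        } else {
          for (int r = 0; r < 48; ++r)
            Ke[r * 48 + k] = (Rp[r] - Re[r]) / step;
        }
      }
      if (!ok) break;
      for (int r = 0; r < 48; ++r)
        for (int c = 0; c < 48; ++c)
          if (Ke[r * 48 + c] != 0.0) {
            ti.push_back(gdof[r] + 1);
            tj.push_back(gdof[c] + 1);
            tx.push_back(Ke[r * 48 + c]);
          }
    }
  }
  return List::create(_["ok"] = ok, _["R"] = Rg, _["h_new"] = hnew_out,
                      _["p_elem"] = pel, _["theta_elem"] = thel,
                      _["i"] = ti, _["j"] = tj, _["x"] = tx);
}

namespace {
// Follower pressure residual on one bilinear facet (deformed configuration).
// Facet node order must give t_xi x t_eta = outward normal of the solid.
void facet_pressure(const mat& Xf, const vec& uf, double pval, vec& Rf) {
  const double s2[4][2] = {{-1, -1}, {1, -1}, {1, 1}, {-1, 1}};
  Rf.zeros(12);
  for (int gp = 0; gp < 4; ++gp) {
    const double xi = s2[gp][0] * GLOC, eta = s2[gp][1] * GLOC;
    double N[4], dxi[4], deta[4];
    arma::vec3 t1(arma::fill::zeros), t2(arma::fill::zeros);
    for (int a = 0; a < 4; ++a) {
      N[a] = 0.25 * (1 + s2[a][0] * xi) * (1 + s2[a][1] * eta);
      dxi[a] = 0.25 * s2[a][0] * (1 + s2[a][1] * eta);
      deta[a] = 0.25 * (1 + s2[a][0] * xi) * s2[a][1];
      for (int i = 0; i < 3; ++i) {
        const double x = Xf(a, i) + uf(a * 3 + i);
        t1(i) += dxi[a] * x;
        t2(i) += deta[a] * x;
      }
    }
    const arma::vec3 cr = arma::cross(t1, t2);
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) Rf(a * 3 + i) += pval * N[a] * cr(i);
  }
}
}  // namespace

// Residual and FD tangent of the follower pressure load over a facet set.
// facets: nf x 4, 1-based node ids, oriented so that the surface normal
// points out of the solid.
// [[Rcpp::export]]
List fem_pressure_load(const arma::mat& nodes, const arma::imat& facets,
                       const arma::vec& pvec, double pval, bool want_tangent,
                       double fd_eps) {
  const int nf = facets.n_rows;
  const int ndof = 6 * nodes.n_rows;
  arma::vec Rg(ndof, arma::fill::zeros);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  mat Xf(4, 3);
  vec uf(12), Rf(12), Rp(12), Rm(12);
  std::vector<int> gdof(12);
  for (int f = 0; f < nf; ++f) {
    for (int a = 0; a < 4; ++a) {
      const int n = facets(f, a) - 1;
      for (int i = 0; i < 3; ++i) {
        Xf(a, i) = nodes(n, i);
        uf(a * 3 + i) = pvec(n * 6 + i);
        gdof[a * 3 + i] = n * 6 + i;
      }
    }
    facet_pressure(Xf, uf, pval, Rf);
    for (int k = 0; k < 12; ++k) Rg(gdof[k]) += Rf(k);
    if (want_tangent) {
      for (int k = 0; k < 12; ++k) {
        const double h0 = uf(k);
        const double step = fd_eps * (1.0 + std::fabs(h0));
        uf(k) = h0 + step;
        facet_pressure(Xf, uf, pval, Rp);
        uf(k) = h0 - step;
        facet_pressure(Xf, uf, pval, Rm);
        uf(k) = h0;
        for (int r = 0; r < 12; ++r) {
          const double v = (Rp(r) - Rm(r)) / (2.0 * step);
          if (v != 0.0) {
            ti.push_back(gdof[r] + 1);
            tj.push_back(gdof[k] + 1);
            tx.push_back(v);
          }
        }
      }
    }
  }
  return List::create(_["R"] = Rg, _["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// Per-Gauss-point report: J, rho0, f_rho, detJ0, lambda_e per family,
// von Mises Cauchy stress.
// [[Rcpp::export]]
arma::mat cpp_gp_report(const arma::mat& nodes, const arma::imat& elems,
                        const arma::vec& pvec, const arma::mat& h,
                        const arma::mat& fib, const arma::vec& par,
                        const arma::vec& pel) {
  const Pars P = unpack_pars(par);
  const int nel = elems.n_rows;
  arma::mat out(nel * 8, 4 + P.nF + 1);
  double N[8], dN[8][3];
  for (int e = 0; e < nel; ++e) {
    double X[8][3], ue[24], cMo[8], cMa[8];
    for (int a = 0; a < 8; ++a) {
      const int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        X[a][i] = nodes(n, i);
        ue[a * 3 + i] = pvec(n * 6 + i);
      }
      cMo[a] = pvec(n * 6 + 4);
      cMa[a] = pvec(n * 6 + 5);
    }
    for (int gp = 0; gp < 8; ++gp) {
      shape_hex(SGN[gp][0] * GLOC, SGN[gp][1] * GLOC, SGN[gp][2] * GLOC,
                N, dN);
      double Jac[9];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int a = 0; a < 8; ++a) s += X[a][i] * dN[a][j];
          Jac[i * 3 + j] = s;
        }
      double Jinv[9];
      const double dj = inv3(Jac, Jinv);
      double dNdX[8][3];
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          dNdX[a][i] = dN[a][0] * Jinv[i] + dN[a][1] * Jinv[3 + i] +
                       dN[a][2] * Jinv[6 + i];
      double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
      double vMo = 0, vMa = 0;
      for (int a = 0; a < 8; ++a) {
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            F[i * 3 + j] += ue[a * 3 + i] * dNdX[a][j];
        vMo += N[a] * cMo[a];
        vMa += N[a] * cMa[a];
      }
      const size_t row = (size_t)e * 8 + gp;
      double hh[7];
      for (int k = 0; k < 7; ++k) hh[k] = h(row, k);
      const double rho0 =
          P.rho0m + hh[2] + P.alpha * ((vMo + vMa) * P.scaleC + hh[0] + hh[1]);
      double C[9];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int k = 0; k < 3; ++k) s += F[k * 3 + i] * F[k * 3 + j];
          C[i * 3 + j] = s;
        }
      double Finv[9], FinvT[9];
      const double J = inv3(F, Finv);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) FinvT[i * 3 + j] = Finv[j * 3 + i];
      out(row, 0) = J;
      out(row, 1) = rho0;
      out(row, 2) = plaque_frho(rho0 / P.rho00, P.rho_tilde);
      out(row, 3) = dj;
      std::vector<double> fr(3 * P.nF);
      for (int j = 0; j < P.nF; ++j)
        for (int i = 0; i < 3; ++i) fr[3 * j + i] = fib(row, 3 * j + i);
      for (int j = 0; j < P.nF; ++j) {
        const double* a = fr.data() + 3 * j;
        double aCa = 0;
        for (int i = 0; i < 3; ++i)
          for (int k = 0; k < 3; ++k) aCa += a[i] * C[i * 3 + k] * a[k];
        out(row, 4 + j) = std::sqrt(aCa) / hh[3 + j];
      }
      double Pk[9];
      pk1_core(F, C, J, FinvT, hh, fr.data(), rho0, pel(e), P, Pk);
      // sigma = P F^T / J, von Mises of its deviator
      double sig[9];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int k = 0; k < 3; ++k) s += Pk[i * 3 + k] * F[j * 3 + k];
          sig[i * 3 + j] = s / J;
        }
      const double tr3 = (sig[0] + sig[4] + sig[8]) / 3.0;
      sig[0] -= tr3; sig[4] -= tr3; sig[8] -= tr3;
      double ss = 0;
      for (int k = 0; k < 9; ++k) ss += sig[k] * sig[k];
      out(row, 4 + P.nF) = std::sqrt(1.5 * ss);
    }
  }
  return out;
}

// Reference-configuration quadrature data: per-GP detJ and interpolated
// values of a per-node scalar field.
// [[Rcpp::export]]
arma::mat cpp_gp_interp(const arma::mat& nodes, const arma::imat& elems,
                        const arma::vec& nodal) {
  const int nel = elems.n_rows;
  arma::mat out(nel * 8, 2);
  double N[8], dN[8][3];
  for (int e = 0; e < nel; ++e) {
    double X[8][3], v[8];
    for (int a = 0; a < 8; ++a) {
      const int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) X[a][i] = nodes(n, i);
      v[a] = nodal(n);
    }
    for (int gp = 0; gp < 8; ++gp) {
      shape_hex(SGN[gp][0] * GLOC, SGN[gp][1] * GLOC, SGN[gp][2] * GLOC,
                N, dN);
      double Jac[9];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int a = 0; a < 8; ++a) s += X[a][i] * dN[a][j];
          Jac[i * 3 + j] = s;
        }
      double val = 0;
      for (int a = 0; a < 8; ++a) val += N[a] * v[a];
      out((size_t)e * 8 + gp, 0) = det3(Jac);
      out((size_t)e * 8 + gp, 1) = val;
    }
  }
  return out;
}
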