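// Orthotropic myocardial constitutive kernels (Holzapfel-Ogden type).
//
// Internal unit system is CGS: stresses in dyne/cm^2, lengths in cm.
// Parameter vector layout (see R/materials.R):
//   p = [a, b, a_f, b_f, a_s, b_s, a_fs, b_fs, beta_s]
// with a, a_i, beta_s in dyne/cm^2 and b, b_i dimensionless.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Strain energy density (reference-volume based, dyne/cm^2 == erg/cm^3).
// The isotropic exponential is shifted by its value at F = I so that the
// reference configuration carries zero stored energy; stresses are
// unaffected by the constant.
static double ho_energy_core(const mat33 &F, const vec3 &f0, const vec3 &s0,
                             const double *p) {
  const double a = p[0], b = p[1], af = p[2], bf = p[3], as_ = p[4],
               bs = p[5], afs = p[6], bfs = p[7];
  mat33 C = F.t() * F;
  double I1 = trace(C);
  double I4f = as_scalar(f0.t() * C * f0);
  double I4s = as_scalar(s0.t() * C * s0);
  double I8 = as_scalar(f0.t() * C * s0);
  double W = a / (2.0 * b) * (std::exp(b * (I1 - 3.0)) - 1.0);
  double e4f = std::max(I4f, 1.0) - 1.0;
  double e4s = std::max(I4s, 1.0) - 1.0;
  W += af / (2.0 * bf) * (std::exp(bf * e4f * e4f) - 1.0);
  W += as_ / (2.0 * bs) * (std::exp(bs * e4s * e4s) - 1.0);
  W += afs / (2.0 * bfs) * (std::exp(bfs * I8 * I8) - 1.0);
  return W;
}

// dW/dF for the energy above.  The clamp max(I4,1) has a one-sided
// derivative taken as zero at I4 = 1 (continuous stress).
static mat33 ho_dWdF_core(const mat33 &F, const vec3 &f0, const vec3 &s0,
                          const double *p) {
  const double a = p[0], b = p[1], af = p[2], bf = p[3], as_ = p[4],
               bs = p[5], afs = p[6], bfs = p[7];
  mat33 C = F.t() * F;
  double I1 = trace(C);
  double I4f = as_scalar(f0.t() * C * f0);
  double I4s = as_scalar(s0.t() * C * s0);
  double I8 = as_scalar(f0.t() * C * s0);

  mat33 P = a * std::exp(b * (I1 - 3.0)) * F;
  if (I4f > 1.0) {
    double e = I4f - 1.0;
    P += 2.0 * af * e * std::exp(bf * e * e) * (F * (f0 * f0.t()));
  }
  if (I4s > 1.0) {
    double e = I4s - 1.0;
    P += 2.0 * as_ * e * std::exp(bs * e * e) * (F * (s0 * s0.t()));
  }
  P += afs * I8 * std::exp(bfs * I8 * I8) *
       (F * (f0 * s0.t() + s0 * f0.t()));
  return P;
}

// Full working passive stress (first Piola-Kirchhoff), including the
// pressure-like reference term and the volumetric penalty, with the
// infarct stiffening (1 + 49 M) applied to the material response but not
// to the numerical penalty.
static mat33 ho_pk1_core(const mat33 &F, const vec3 &f0, const vec3 &s0,
                         const double *p, double M) {
  const double a = p[0], b = p[1], beta_s = p[8];
  double J = det(F);
  if (!(J > 0.0)) Rcpp::stop("invalid deformation: det(F) <= 0");
  mat33 Finvt = inv(F).t();
  mat33 C = F.t() * F;
  double I1 = trace(C);
  double I3 = J * J;
  double stiff = 1.0 + 49.0 * M;
  mat33 P = stiff * (ho_dWdF_core(F, f0, s0, p) -
                     a * std::exp(b * (I1 - 3.0)) * Finvt);
  P += beta_s * std::log(I3) * Finvt;
  return P;
}

// [[Rcpp::export]]
Rcpp::List cpp_ho_invariants(const arma::mat &F, const arma::vec &f0,
                             const arma::vec &s0) {
  mat33 Fm = F;
  double J = det(Fm);
  if (!(J > 0.0)) Rcpp::stop("invalid deformation: det(F) <= 0");
  mat33 C = Fm.t() * Fm;
  vec3 f = Fm * vec3(f0), s = Fm * vec3(s0);
  double I4f = dot(f, f), I4s = dot(s, s);
  return Rcpp::List::create(
      Rcpp::Named("J") = J, Rcpp::Named("I1") = trace(C),
      Rcpp::Named("I3") = J * J, Rcpp::Named("I4f") = I4f,
      Rcpp::Named("I4s") = I4s, Rcpp::Named("I8fs") = dot(f, s),
      Rcpp::Named("I4f_star") = std::max(I4f, 1.0),
      Rcpp::Named("I4s_star") = std::max(I4s, 1.0),
      Rcpp::Named("f") = f, Rcpp::Named("s") = s,
      Rcpp::Named("lambda_f") = std::sqrt(I4f),
      Rcpp::Named("lambda_s") = std::sqrt(I4s));
}

// [[Rcpp::export]]
double cpp_ho_energy(const arma::mat &F, const arma::vec &f0,
                     const arma::vec &s0, const arma::vec &par, double M) {
  mat33 Fm = F;
  if (!(det(Fm) > 0.0)) Rcpp::stop("invalid deformation: det(F) <= 0");
  return (1.0 + 49.0 * M) * ho_energy_core(Fm, vec3(f0), vec3(s0), par.memptr());
}

// [[Rcpp::export]]
arma::mat cpp_ho_dWdF(const arma::mat &F, const arma::vec &f0,
                      const arma::vec &s0, const arma::vec &par, double M) {
  mat33 Fm = F;
  return (1.0 + 49.0 * M) * ho_dWdF_core(Fm, vec3(f0), vec3(s0), par.memptr());
}

// [[Rcpp::export]]
arma::mat cpp_ho_pk1(const arma::mat &F, const arma::vec &f0,
                     const arma::vec &s0, const arma::vec &par, double M) {
  mat33 Fm = F;
  return ho_pk1_core(Fm, vec3(f0), vec3(s0), par.memptr(), M);
}

// [[Rcpp::export]]
arma::mat cpp_active_pk1(const arma::mat &F, const arma::vec &f0, double T) {
  mat33 Fm = F;
  double J = det(Fm);
  vec3 f0v = f0;
  return J * T * (Fm * (f0v * f0v.t()));
}

// Bulk evaluation over elements: Fs is n x 9 (column-major flattened 3x3),
// returns n x 9 total structural PK1 (passive + active).  Tact must
// already include T_scale and the (1 - M) contractility factor.
// Hand-rolled 3x3 algebra: this is the per-step constitutive hot loop.
// [[Rcpp::export]]
arma::mat cpp_pk1_bulk(const arma::mat &Fs, const arma::mat &f0s,
                       const arma::mat &s0s, const arma::vec &par,
                       const arma::vec &M, const arma::vec &Tact) {
  const uword n = Fs.n_rows;
  mat out(n, 9);
  const double a = par(0), b = par(1), af = par(2), bf = par(3),
               as_ = par(4), bs = par(5), afs = par(6), bfs = par(7),
               beta_s = par(8);
  for (uword e = 0; e < n; ++e) {
    double F[9];
    for (int c = 0; c < 9; ++c) F[c] = Fs(e, c); // column-major
    const double f01 = f0s(e, 0), f02 = f0s(e, 1), f03 = f0s(e, 2);
    const double s01 = s0s(e, 0), s02 = s0s(e, 1), s03 = s0s(e, 2);
    // f = F f0, s = F s0
    const double f1 = F[0] * f01 + F[3] * f02 + F[6] * f03;
    const double f2 = F[1] * f01 + F[4] * f02 + F[7] * f03;
    const double f3 = F[2] * f01 + F[5] * f02 + F[8] * f03;
    const double sv1 = F[0] * s01 + F[3] * s02 + F[6] * s03;
    const double sv2 = F[1] * s01 + F[4] * s02 + F[7] * s03;
    const double sv3 = F[2] * s01 + F[5] * s02 + F[8] * s03;
    const double I1 = F[0] * F[0] + F[1] * F[1] + F[2] * F[2] +
                      F[3] * F[3] + F[4] * F[4] + F[5] * F[5] +
                      F[6] * F[6] + F[7] * F[7] + F[8] * F[8];
    const double I4f = f1 * f1 + f2 * f2 + f3 * f3;
    const double I4s = sv1 * sv1 + sv2 * sv2 + sv3 * sv3;
    const double I8 = f1 * sv1 + f2 * sv2 + f3 * sv3;
    // cofactors / determinant / inverse-transpose
    const double c0 = F[4] * F[8] - F[7] * F[5];
    const double c1 = F[7] * F[2] - F[1] * F[8];
    const double c2 = F[1] * F[5] - F[4] * F[2];
    const double c3 = F[6] * F[5] - F[3] * F[8];
    const double c4 = F[0] * F[8] - F[6] * F[2];
    const double c5 = F[3] * F[2] - F[0] * F[5];
    const double c6 = F[3] * F[7] - F[6] * F[4];
    const double c7 = F[6] * F[1] - F[0] * F[7];
    const double c8 = F[0] * F[4] - F[3] * F[1];
    const double J = F[0] * c0 + F[3] * c1 + F[6] * c2;
    if (!(J > 0.0)) Rcpp::stop("invalid deformation: det(F) <= 0 in element %d", (int)e + 1);
    const double invJ = 1.0 / J;
    // F^{-T} = cof(F)/J, with cof in column-major of F^{-T}
    const double Fit[9] = {c0 * invJ, c3 * invJ, c6 * invJ,
                           c1 * invJ, c4 * invJ, c7 * invJ,
                           c2 * invJ, c5 * invJ, c8 * invJ};
    const double stiff = 1.0 + 49.0 * M(e);
    const double g1 = a * std::exp(b * (I1 - 3.0));
    double g4f = 0.0, g4s = 0.0;
    if (I4f > 1.0) {
      const double ef = I4f - 1.0;
      g4f = 2.0 * af * ef * std::exp(bf * ef * ef);
    }
    if (I4s > 1.0) {
      const double es = I4s - 1.0;
      g4s = 2.0 * as_ * es * std::exp(bs * es * es);
    }
    const double g8 = afs * I8 * std::exp(bfs * I8 * I8);
    const double vterm = beta_s * 2.0 * std::log(J);
    const double Ta = Tact(e);
    const double cf = stiff * g4f + J * Ta; // coefficient of f (x) f0
    double P[9];
    const double fvec[3] = {f1, f2, f3}, svec[3] = {sv1, sv2, sv3};
    const double f0v[3] = {f01, f02, f03}, s0v[3] = {s01, s02, s03};
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) {
        double v = stiff * g1 * F[3 * c + r] +
                   cf * fvec[r] * f0v[c] +
                   stiff * (g4s * svec[r] * s0v[c] +
                            g8 * (fvec[r] * s0v[c] + svec[r] * f0v[c]) -
                            g1 * Fit[3 * c + r]) +
                   vterm * Fit[3 * c + r];
        P[3 * c + r] = v;
      }
    for (int c = 0; c < 9; ++c) out(e, c) = P[c];
  }
  return out;
}

// Bulk strain energy (per element), used for energy-gradient audits.
// [[Rcpp::export]]
arma::vec cpp_energy_bulk(const arma::mat &Fs, const arma::mat &f0s,
                          const arma::mat &s0s, const arma::vec &par,
                          const arma::vec &M, bool with_penalty) {
  const uword n = Fs.n_rows;
  vec out(n);
  const double *p = par.memptr();
  const double beta_s = p[8];
  for (uword e = 0; e < n; ++e) {
    mat33 F;
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) F(r, c) = Fs(e, 3 * c + r);
    vec3 f0 = f0s.row(e).t(), s0 = s0s.row(e).t();
    double W = (1.0 + 49.0 * M(e)) * ho_energy_core(F, f0, s0, p);
    if (with_penalty) {
      double J = det(F);
      double lI3 = std::log(J * J);
      W += 0.25 * beta_s * lI3 * lI3;
    }
    out(e) = W;
  }
  return out;
}
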