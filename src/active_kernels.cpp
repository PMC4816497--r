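// Active tension generation: length- and velocity-dependent contraction
// model with calcium-troponin binding kinetics, a tropomyosin activation
// gate, and fading-memory crossbridge dynamics.
//
// State vector per material point: (CaTRPN [uM], z, Q1, Q2, Q3).
// Tension is returned in kPa (cell-model units); callers convert to CGS
// and apply T_scale and the infarct contractility factor (1 - M).
//
// Parameter vector layout (see R/active.R):
//  0 T_ref (kPa)     1 k_on (1/uM/s)  2 k_off_ref (1/s)  3 gamma_trpn
//  4 CaTRPN_max (uM) 5 ca50_ref (uM)  6 n_hill           7 alpha0 (1/s)
//  8 alpha_r1 (1/s)  9 alpha_r2 (1/s) 10 K_Z             11 n_r
// 12 beta0          13 beta1          14 a_xb
// 15 A1 16 A2 17 A3 18 alpha1 19 alpha2 20 alpha3 (1/s)
// 21 lambda_min     22 lambda_max

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// pow with a fast path for small integer exponents (the cooperativity
// exponents are 3 in the default parameter set)
static inline double powq(double x, double n) {
  int ni = (int)n;
  if (ni == n && ni >= 0 && ni <= 4) {
    double r = 1.0;
    for (int i = 0; i < ni; ++i) r *= x;
    return r;
  }
  return std::pow(x, n);
}

static inline double ca_trpn50(double lam, const double *p) {
  const double kon = p[1], koff = p[2], gam = p[3], camax = p[4],
               ca50r = p[5], b0 = p[12], b1 = p[13];
  double ca50 = ca50r * (1.0 + b1 * (lam - 1.0));
  double denom = ca50 + (koff / kon) * (1.0 - (1.0 + b0 * (lam - 1.0)) / (2.0 * gam));
  return camax * ca50 / denom;
}

// dz/dt at a given troponin loading.
static inline double z_rate(double z, double catrpn, double lam,
                            const double *p) {
  const double a0 = p[7], ar1 = p[8], ar2 = p[9], Kz = p[10], nr = p[11],
               nh = p[6];
  double gate = a0 * powq(catrpn / ca_trpn50(lam, p), nh);
  double zn = powq(z, nr);
  return gate * (1.0 - z) - ar1 * z - ar2 * zn / (zn + powq(Kz, nr));
}

// Steady-state z at full troponin loading (CaTRPN = CaTRPN_max) at the
// given stretch; solved by bisection (the rate is strictly decreasing
// in z on [0, 1]).
// [[Rcpp::export]]
double cpp_nhs_zmax(double lambda, const arma::vec &par) {
  const double *p = par.memptr();
  double lam = clamp(lambda, p[21], p[22]);
  // Newton with a bisection safeguard: the rate is strictly decreasing
  // in z on [0, 1]
  double lo = 0.0, hi = 1.0, z = 0.95;
  for (int it = 0; it < 60; ++it) {
    double f = z_rate(z, p[4], lam, p);
    if (f > 0.0) lo = z; else hi = z;
    const double dz = 1e-7;
    double df = (z_rate(z + dz, p[4], lam, p) - f) / dz;
    double zn = (df < 0.0) ? z - f / df : 0.5 * (lo + hi);
    if (zn <= lo || zn >= hi) zn = 0.5 * (lo + hi);
    if (std::fabs(zn - z) < 1e-14) return zn;
    z = zn;
  }
  return z;
}

// Isometric tension (before crossbridge velocity correction) from the
// activation gate, normalized so that full activation yields
// T_ref * (1 + beta0 (lambda - 1)).
static inline double t0_tension(double z, double lam, double zmax,
                                const double *p) {
  double lenf = 1.0 + p[12] * (lam - 1.0);
  if (lenf < 0.0) lenf = 0.0;
  return p[0] * lenf * z / zmax;
}

static inline double q_correction(double T0, double Q, double a_xb) {
  if (Q < 0.0) return T0 * (a_xb * Q + 1.0) / (1.0 - Q);
  return T0 * (1.0 + (a_xb + 2.0) * Q) / (1.0 + Q);
}

// Advance a block of active states by dt (with nsub equal substeps).
// Exponential updates are used for the linear troponin-binding and
// fading-memory equations; the activation gate uses explicit Euler.
// Returns the updated states and the scaled tension scale * T (kPa).
// [[Rcpp::export]]
Rcpp::List cpp_nhs_step_bulk(const arma::mat &states, const arma::vec &lambda,
                             const arma::vec &dlambda, double Ca, double dt,
                             int nsub, const arma::vec &par,
                             const arma::vec &scale) {
  const double *p = par.memptr();
  const uword n = states.n_rows;
  if (nsub < 1) nsub = 1;
  const double h = dt / nsub;
  mat st = states;
  vec Tout(n);
  for (uword i = 0; i < n; ++i) {
    double lam = clamp(lambda(i), p[21], p[22]);
    double dl = dlambda(i);
    double zmax = cpp_nhs_zmax(lam, par);
    double catrpn = st(i, 0), z = st(i, 1);
    double Q1 = st(i, 2), Q2 = st(i, 3), Q3 = st(i, 4);
    double T = 0.0;
    for (int s = 0; s < nsub; ++s) {
      double T0 = t0_tension(z, lam, zmax, p);
      T = q_correction(T0, Q1 + Q2 + Q3, p[14]);
      if (T < 0.0) T = 0.0;
      // tension-dependent calcium unbinding, exact exponential update
      double koff = p[2] * std::max(0.05, 1.0 - T / (p[3] * p[0]));
      double r = p[1] * Ca + koff;
      double cinf = p[1] * Ca * p[4] / r;
      catrpn = cinf + (catrpn - cinf) * std::exp(-r * h);
      z += h * z_rate(z, catrpn, lam, p);
      z = clamp(z, 0.0, 1.0);
      // fading-memory crossbridge variables, exact for constant dlambda
      const double A[3] = {p[15], p[16], p[17]};
      const double al[3] = {p[18], p[19], p[20]};
      double *Q[3] = {&Q1, &Q2, &Q3};
      for (int k = 0; k < 3; ++k) {
        double ex = std::exp(-al[k] * h);
        *Q[k] = *Q[k] * ex + A[k] * dl * (1.0 - ex) / al[k];
      }
    }
    double T0 = t0_tension(z, lam, zmax, p);
    T = q_correction(T0, Q1 + Q2 + Q3, p[14]);
    if (T < 0.0) T = 0.0;
    st(i, 0) = catrpn; st(i, 1) = z;
    st(i, 2) = Q1; st(i, 3) = Q2; st(i, 4) = Q3;
    Tout(i) = scale(i) * T;
  }
  return Rcpp::List::create(Rcpp::Named("states") = st,
                            Rcpp::Named("T") = Tout);
}

// Tension implied by a state without advancing it (kPa, unscaled).
// [[Rcpp::export]]
arma::vec cpp_nhs_tension(const arma::mat &states, const arma::vec &lambda,
                          const arma::vec &par) {
  const double *p = par.memptr();
  const uword n = states.n_rows;
  vec out(n);
  for (uword i = 0; i < n; ++i) {
    double lam = clamp(lambda(i), p[21], p[22]);
    double zmax = cpp_nhs_zmax(lam, par);
    double T = q_correction(t0_tension(states(i, 1), lam, zmax, p),
                            states(i, 2) + states(i, 3) + states(i, 4), p[14]);
    out(i) = T < 0.0 ? 0.0 : T;
  }
  return out;
}
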