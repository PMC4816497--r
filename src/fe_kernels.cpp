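// Total-Lagrangian finite element kernels on linear tetrahedra.
//
// Elements are 0-based index matrices (converted on the R side).
// Reference shape-function gradients are precomputed once per mesh.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Reference shape-function gradients (4 x 3 per element, stored as a row
// of 12: gradN[a, :] = d phi_a / dX) and signed reference volumes.
// [[Rcpp::export]]
Rcpp::List cpp_tet_precompute(const arma::mat &X, const arma::imat &elems) {
  const uword m = elems.n_rows;
  mat gradN(m, 12);
  vec V0(m);
  for (uword e = 0; e < m; ++e) {
    mat33 D;
    vec3 x0 = X.row(elems(e, 0)).t();
    for (int a = 0; a < 3; ++a)
      D.col(a) = X.row(elems(e, a + 1)).t() - x0;
    double detD = det(D);
    V0(e) = detD / 6.0;
    if (std::abs(detD) < 1e-300)
      Rcpp::stop("degenerate tetrahedron (zero volume), element %d", (int)e + 1);
    mat33 Dinv = inv(D);
    // grad phi_{a+1} = row a of Dinv; grad phi_1 = -sum
    rowvec3 g1(fill::zeros);
    for (int a = 0; a < 3; ++a) {
      rowvec3 g = Dinv.row(a);
      g1 -= g;
      for (int c = 0; c < 3; ++c) gradN(e, 3 * (a + 1) + c) = g(c);
    }
    for (int c = 0; c < 3; ++c) gradN(e, c) = g1(c);
  }
  return Rcpp::List::create(Rcpp::Named("gradN") = gradN,
                            Rcpp::Named("V0") = V0);
}

// Per-element deformation gradient F = sum_a x_a (grad phi_a)^T,
// returned as m x 9 column-major flattened 3x3 blocks.
// [[Rcpp::export]]
arma::mat cpp_tet_defgrad(const arma::mat &x, const arma::imat &elems,
                          const arma::mat &gradN) {
  const uword m = elems.n_rows;
  mat F(m, 9, fill::zeros);
  for (uword e = 0; e < m; ++e) {
    for (int a = 0; a < 4; ++a) {
      const uword nid = elems(e, a);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          F(e, 3 * j + i) += x(nid, i) * gradN(e, 3 * a + j);
    }
  }
  return F;
}

// Galerkin internal nodal forces of the weak form: G_a = -V0 * P gradphi_a.
// [[Rcpp::export]]
arma::mat cpp_fe_internal_force(const arma::imat &elems, const arma::mat &gradN,
                                const arma::vec &V0, const arma::mat &P,
                                int nnodes) {
  mat G(nnodes, 3, fill::zeros);
  const uword m = elems.n_rows;
  for (uword e = 0; e < m; ++e) {
    mat33 Pe;
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) Pe(r, c) = P(e, 3 * c + r);
    if (!Pe.is_finite())
      Rcpp::stop("non-finite stress in element %d", (int)e + 1);
    for (int a = 0; a < 4; ++a) {
      vec3 g = {gradN(e, 3 * a), gradN(e, 3 * a + 1), gradN(e, 3 * a + 2)};
      vec3 f = -V0(e) * (Pe * g);
      const uword nid = elems(e, a);
      for (int i = 0; i < 3; ++i) G(nid, i) += f(i);
    }
  }
  return G;
}

// Follower pressure load on triangulated faces of the deformed surface:
// traction -p n per unit current area, n the outward surface normal of
// the solid given by the stored winding of each triangle.
// [[Rcpp::export]]
arma::mat cpp_pressure_force(const arma::mat &x, const arma::imat &tris,
                             double p, int nnodes) {
  mat G(nnodes, 3, fill::zeros);
  if (p == 0.0) return G;
  for (uword t = 0; t < tris.n_rows; ++t) {
    vec3 x1 = x.row(tris(t, 0)).t();
    vec3 x2 = x.row(tris(t, 1)).t();
    vec3 x3 = x.row(tris(t, 2)).t();
    vec3 A = 0.5 * cross(x2 - x1, x3 - x1); // outward area vector
    vec3 f = (-p / 3.0) * A;
    for (int a = 0; a < 3; ++a) {
      const uword nid = tris(t, a);
      for (int i = 0; i < 3; ++i) G(nid, i) += f(i);
    }
  }
  return G;
}

// Lumped nodal reference volumes (row-sum mass lumping).
// [[Rcpp::export]]
arma::vec cpp_lumped_volume(const arma::imat &elems, const arma::vec &V0,
                            int nnodes) {
  vec vol(nnodes, fill::zeros);
  for (uword e = 0; e < elems.n_rows; ++e)
    for (int a = 0; a < 4; ++a) vol(elems(e, a)) += V0(e) / 4.0;
  return vol;
}

// Interior barycentric-lattice quadrature.  For element e with lattice
// order k(e), points have barycentric coordinates (i+1/4)/(k+1) over all
// nonneg. integer 4-tuples summing to k, with equal weights V0/npts.
// The rule is permutation-symmetric, hence exact for affine integrands.
// Points are mapped through the *current* nodal positions x.
// [[Rcpp::export]]
Rcpp::List cpp_quad_points(const arma::mat &x, const arma::imat &elems,
                           const arma::vec &V0, const arma::ivec &order) {
  const uword m = elems.n_rows;
  uword total = 0;
  std::vector<uword> npts(m);
  for (uword e = 0; e < m; ++e) {
    uword k = (uword)std::max(0, (int)order(e));
    npts[e] = (k + 1) * (k + 2) * (k + 3) / 6;
    total += npts[e];
  }
  mat pts(total, 3);
  vec w(total);
  ivec eid(total);
  uword q = 0;
  for (uword e = 0; e < m; ++e) {
    const int k = std::max(0, (int)order(e));
    mat xe4(4, 3);
    for (int a = 0; a < 4; ++a) xe4.row(a) = x.row(elems(e, a));
    const double wq = V0(e) / npts[e];
    for (int i = 0; i <= k; ++i)
      for (int j = 0; j <= k - i; ++j)
        for (int l = 0; l <= k - i - j; ++l) {
          int r = k - i - j - l;
          double b[4] = {(i + 0.25) / (k + 1.0), (j + 0.25) / (k + 1.0),
                         (l + 0.25) / (k + 1.0), (r + 0.25) / (k + 1.0)};
          rowvec3 pnt(fill::zeros);
          for (int a = 0; a < 4; ++a) pnt += b[a] * xe4.row(a);
          pts.row(q) = pnt;
          w(q) = wq;
          eid(q) = (int)e + 1; // 1-based for R
          ++q;
        }
  }
  return Rcpp::List::create(Rcpp::Named("points") = pts,
                            Rcpp::Named("weights") = w,
                            Rcpp::Named("element") = eid);
}

// Exact minimum distance from each query point to a triangulated surface
// (Eberly's region decomposition for point-triangle distance).
static double point_tri_dist2(const vec3 &P, const vec3 &B, const vec3 &E0,
                              const vec3 &E1) {
  vec3 D = B - P;
  double a = dot(E0, E0), b = dot(E0, E1), c = dot(E1, E1);
  double d = dot(E0, D), e = dot(E1, D), f = dot(D, D);
  double det = a * c - b * b, s = b * e - c * d, t = b * d - a * e;
  if (s + t <= det) {
    if (s < 0) {
      if (t < 0) { // region 4
        if (d < 0) { t = 0; s = (-d >= a ? 1 : -d / a); }
        else { s = 0; t = (e >= 0 ? 0 : (-e >= c ? 1 : -e / c)); }
      } else { // region 3
        s = 0; t = (e >= 0 ? 0 : (-e >= c ? 1 : -e / c));
      }
    } else if (t < 0) { // region 5
      t = 0; s = (d >= 0 ? 0 : (-d >= a ? 1 : -d / a));
    } else { // region 0
      double inv = 1.0 / det; s *= inv; t *= inv;
    }
  } else {
    if (s < 0) { // region 2
      double tmp0 = b + d, tmp1 = c + e;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = a - 2 * b + c;
        s = (numer >= denom ? 1 : numer / denom); t = 1 - s;
      } else { s = 0; t = (tmp1 <= 0 ? 1 : (e >= 0 ? 0 : -e / c)); }
    } else if (t < 0) { // region 6
      double tmp0 = b + e, tmp1 = a + d;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = a - 2 * b + c;
        t = (numer >= denom ? 1 : numer / denom); s = 1 - t;
      } else { t = 0; s = (tmp1 <= 0 ? 1 : (d >= 0 ? 0 : -d / a)); }
    } else { // region 1
      double numer = c + e - b - d;
      if (numer <= 0) s = 0;
      else {
        double denom = a - 2 * b + c;
        s = (numer >= denom ? 1 : numer / denom);
      }
      t = 1 - s;
    }
  }
  double dist2 = a * s * s + 2 * b * s * t + c * t * t + 2 * d * s +
                 2 * e * t + f;
  return dist2 < 0 ? 0 : dist2;
}

// [[Rcpp::export]]
arma::vec cpp_point_surface_dist(const arma::mat &pts, const arma::mat &verts,
                                 const arma::imat &tris) {
  const uword n = pts.n_rows, m = tris.n_rows;
  vec out(n);
  for (uword i = 0; i < n; ++i) {
    vec3 P = pts.row(i).t();
    double best = datum::inf;
    for (uword t = 0; t < m; ++t) {
      vec3 B = verts.row(tris(t, 0)).t();
      vec3 E0 = verts.row(tris(t, 1)).t() - B;
      vec3 E1 = verts.row(tris(t, 2)).t() - B;
      double d2 = point_tri_dist2(P, B, E0, E1);
      if (d2 < best) best = d2;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}

// Combined quadrature + force sampling for the IB spreading step:
// regenerates the lattice points of cpp_quad_points and linearly
// interpolates the nodal force density, returning per-point forces
// already multiplied by the quadrature weights.
// [[Rcpp::export]]
Rcpp::List cpp_quad_forces(const arma::mat &x, const arma::imat &elems,
                           const arma::vec &V0, const arma::ivec &order,
                           const arma::mat &nodal) {
  const uword m = elems.n_rows;
  uword total = 0;
  std::vector<uword> npts(m);
  for (uword e = 0; e < m; ++e) {
    uword k = (uword)std::max(0, (int)order(e));
    npts[e] = (k + 1) * (k + 2) * (k + 3) / 6;
    total += npts[e];
  }
  mat pts(total, 3), val(total, 3);
  uword q = 0;
  for (uword e = 0; e < m; ++e) {
    const int k = std::max(0, (int)order(e));
    mat xe(4, 3), fe(4, 3);
    for (int a = 0; a < 4; ++a) {
      xe.row(a) = x.row(elems(e, a));
      fe.row(a) = nodal.row(elems(e, a));
    }
    const double wq = V0(e) / npts[e];
    for (int i = 0; i <= k; ++i)
      for (int j = 0; j <= k - i; ++j)
        for (int l = 0; l <= k - i - j; ++l) {
          int r = k - i - j - l;
          double b[4] = {(i + 0.25) / (k + 1.0), (j + 0.25) / (k + 1.0),
                         (l + 0.25) / (k + 1.0), (r + 0.25) / (k + 1.0)};
          rowvec3 pnt(fill::zeros), f(fill::zeros);
          for (int a = 0; a < 4; ++a) {
            pnt += b[a] * xe.row(a);
            f += b[a] * fe.row(a);
          }
          pts.row(q) = pnt;
          val.row(q) = wq * f;
          ++q;
        }
  }
  return Rcpp::List::create(Rcpp::Named("points") = pts,
                            Rcpp::Named("forces") = val);
}

// Fibre stretch per element: |F f0|.
// [[Rcpp::export]]
arma::vec cpp_fibre_stretch(const arma::mat &Fs, const arma::mat &f0s) {
  const uword n = Fs.n_rows;
  vec out(n);
  for (uword e = 0; e < n; ++e) {
    double f1 = Fs(e, 0) * f0s(e, 0) + Fs(e, 3) * f0s(e, 1) + Fs(e, 6) * f0s(e, 2);
    double f2 = Fs(e, 1) * f0s(e, 0) + Fs(e, 4) * f0s(e, 1) + Fs(e, 7) * f0s(e, 2);
    double f3 = Fs(e, 2) * f0s(e, 0) + Fs(e, 5) * f0s(e, 1) + Fs(e, 8) * f0s(e, 2);
    out(e) = std::sqrt(f1 * f1 + f2 * f2 + f3 * f3);
  }
  return out;
}

// det(F) per element for inversion checks.
// [[Rcpp::export]]
arma::vec cpp_defgrad_det(const arma::mat &Fs) {
  const uword n = Fs.n_rows;
  vec out(n);
  for (uword e = 0; e < n; ++e) {
    mat33 F;
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) F(r, c) = Fs(e, 3 * c + r);
    out(e) = det(F);
  }
  return out;
}
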