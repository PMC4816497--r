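// Lagrangian-Eulerian transfer operators on a staggered MAC grid using
// the standard four-point regularized delta function.
//
// Grid conventions: nx x ny x nz cells, isotropic spacing dx, origin at
// the lower box corner.  Face-normal velocity components:
//   u: (nx+1, ny, nz) at (i dx, (j+1/2) dx, (k+1/2) dx) + origin
//   v: (nx, ny+1, nz), w: (nx, ny, nz+1) analogously.
// In periodic mode faces i = 0 and i = nx are identified; only indices
// 0..nx-1 are authoritative and the duplicate plane is kept in sync.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double d4(double r) {
  double ar = std::fabs(r);
  if (ar >= 2.0) return 0.0;
  if (ar <= 1.0) return 0.125 * (3.0 - 2.0 * ar + std::sqrt(1.0 + 4.0 * ar - 4.0 * ar * ar));
  return 0.125 * (5.0 - 2.0 * ar - std::sqrt(-7.0 + 12.0 * ar - 4.0 * ar * ar));
}

// [[Rcpp::export]]
arma::vec cpp_delta4(const arma::vec &r) {
  vec out(r.n_elem);
  for (uword i = 0; i < r.n_elem; ++i) out(i) = d4(r(i));
  return out;
}

struct MacGeom {
  int nx, ny, nz;
  double dx, ox, oy, oz;
  bool periodic;
};

// Stencil of the 4 grid indices and weights along one axis for a point at
// grid-scaled coordinate r (in units of dx relative to index 0).
static inline void stencil(double r, int idx[4], double w[4]) {
  int i0 = (int)std::floor(r) - 1;
  for (int k = 0; k < 4; ++k) {
    idx[k] = i0 + k;
    w[k] = d4(r - idx[k]);
  }
}

static inline int wrap(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// comp: 0=u, 1=v, 2=w. Dimensions of the face array for a component.
static inline void face_dims(const MacGeom &g, int comp, int &mx, int &my, int &mz) {
  mx = g.nx + (comp == 0 ? 1 : 0);
  my = g.ny + (comp == 1 ? 1 : 0);
  mz = g.nz + (comp == 2 ? 1 : 0);
}

static void spread_component(const MacGeom &g, int comp, const mat &pts,
                             const vec &val, cube &f) {
  int mx, my, mz;
  face_dims(g, comp, mx, my, mz);
  const double invh3 = 1.0 / (g.dx * g.dx * g.dx);
  for (uword q = 0; q < pts.n_rows; ++q) {
    double rx = (pts(q, 0) - g.ox) / g.dx - (comp == 0 ? 0.0 : 0.5);
    double ry = (pts(q, 1) - g.oy) / g.dx - (comp == 1 ? 0.0 : 0.5);
    double rz = (pts(q, 2) - g.oz) / g.dx - (comp == 2 ? 0.0 : 0.5);
    int ix[4], iy[4], iz[4];
    double wx[4], wy[4], wz[4];
    stencil(rx, ix, wx); stencil(ry, iy, wy); stencil(rz, iz, wz);
    for (int a = 0; a < 4; ++a) {
      int i = ix[a];
      if (g.periodic) i = wrap(i, g.nx);
      else if (i < 0 || i >= mx)
        Rcpp::stop("structure point outside the fluid box (or within the delta-kernel support of its boundary)");
      for (int b = 0; b < 4; ++b) {
        int j = iy[b];
        if (g.periodic) j = wrap(j, g.ny);
        else if (j < 0 || j >= my)
          Rcpp::stop("structure point outside the fluid box (or within the delta-kernel support of its boundary)");
        const double wxy = wx[a] * wy[b];
        if (wxy == 0.0) continue;
        for (int c = 0; c < 4; ++c) {
          int k = iz[c];
          if (g.periodic) k = wrap(k, g.nz);
          else if (k < 0 || k >= mz)
            Rcpp::stop("structure point outside the fluid box (or within the delta-kernel support of its boundary)");
          f(i, j, k) += val(q) * wxy * wz[c] * invh3;
        }
      }
    }
  }
}

static double interp_component(const MacGeom &g, int comp, const cube &f,
                               double x, double y, double z) {
  int mx, my, mz;
  face_dims(g, comp, mx, my, mz);
  double rx = (x - g.ox) / g.dx - (comp == 0 ? 0.0 : 0.5);
  double ry = (y - g.oy) / g.dx - (comp == 1 ? 0.0 : 0.5);
  double rz = (z - g.oz) / g.dx - (comp == 2 ? 0.0 : 0.5);
  int ix[4], iy[4], iz[4];
  double wx[4], wy[4], wz[4];
  stencil(rx, ix, wx); stencil(ry, iy, wy); stencil(rz, iz, wz);
  double out = 0.0;
  for (int a = 0; a < 4; ++a) {
    int i = ix[a];
    if (g.periodic) i = wrap(i, g.nx);
    else if (i < 0 || i >= mx)
      Rcpp::stop("interpolation point outside the fluid box (or within the delta-kernel support of its boundary)");
    for (int b = 0; b < 4; ++b) {
      int j = iy[b];
      if (g.periodic) j = wrap(j, g.ny);
      else if (j < 0 || j >= my)
        Rcpp::stop("interpolation point outside the fluid box (or within the delta-kernel support of its boundary)");
      const double wxy = wx[a] * wy[b];
      if (wxy == 0.0) continue;
      for (int c = 0; c < 4; ++c) {
        int k = iz[c];
        if (g.periodic) k = wrap(k, g.nz);
        else if (k < 0 || k >= mz)
          Rcpp::stop("interpolation point outside the fluid box (or within the delta-kernel support of its boundary)");
        out += f(i, j, k) * wxy * wz[c];
      }
    }
  }
  return out;
}

static MacGeom geom_from(int nx, int ny, int nz, double dx,
                         const arma::vec &origin, bool periodic) {
  MacGeom g;
  g.nx = nx; g.ny = ny; g.nz = nz; g.dx = dx;
  g.ox = origin(0); g.oy = origin(1); g.oz = origin(2);
  g.periodic = periodic;
  return g;
}

static void sync_periodic(cube &u, cube &v, cube &w, const MacGeom &g) {
  if (!g.periodic) return;
  for (int j = 0; j < g.ny; ++j)
    for (int k = 0; k < g.nz; ++k) u(g.nx, j, k) = u(0, j, k);
  for (int i = 0; i < g.nx; ++i)
    for (int k = 0; k < g.nz; ++k) v(i, g.ny, k) = v(i, 0, k);
  for (int i = 0; i < g.nx; ++i)
    for (int j = 0; j < g.ny; ++j) w(i, j, g.nz) = w(i, j, 0);
}

// Spread point forces (already quadrature-weighted, units of force) onto
// the MAC faces as a body-force density field.
// [[Rcpp::export]]
Rcpp::List cpp_spread_mac(const arma::mat &pts, const arma::mat &val, int nx,
                          int ny, int nz, double dx, const arma::vec &origin,
                          bool periodic) {
  MacGeom g = geom_from(nx, ny, nz, dx, origin, periodic);
  cube fu(nx + 1, ny, nz, fill::zeros);
  cube fv(nx, ny + 1, nz, fill::zeros);
  cube fw(nx, ny, nz + 1, fill::zeros);
  spread_component(g, 0, pts, val.col(0), fu);
  spread_component(g, 1, pts, val.col(1), fv);
  spread_component(g, 2, pts, val.col(2), fw);
  sync_periodic(fu, fv, fw, g);
  return Rcpp::List::create(Rcpp::Named("u") = fu, Rcpp::Named("v") = fv,
                            Rcpp::Named("w") = fw);
}

// Interpolate the MAC velocity field to arbitrary points.
// [[Rcpp::export]]
arma::mat cpp_interp_mac(const arma::cube &u, const arma::cube &v,
                         const arma::cube &w, const arma::mat &pts, int nx,
                         int ny, int nz, double dx, const arma::vec &origin,
                         bool periodic) {
  MacGeom g = geom_from(nx, ny, nz, dx, origin, periodic);
  mat out(pts.n_rows, 3);
  for (uword q = 0; q < pts.n_rows; ++q) {
    out(q, 0) = interp_component(g, 0, u, pts(q, 0), pts(q, 1), pts(q, 2));
    out(q, 1) = interp_component(g, 1, v, pts(q, 0), pts(q, 1), pts(q, 2));
    out(q, 2) = interp_component(g, 2, w, pts(q, 0), pts(q, 1), pts(q, 2));
  }
  return out;
}

// ---------------------------------------------------------------------
// Fused fast path for the coupled step: per-element lattice quadrature
// (order chosen from the deformed max edge so spacing <= dx/2),
// linear interpolation of the nodal force density, and spreading to
// the MAC faces, all in one pass.  The four axis weights of the
// 4-point kernel share a single radical:
//   s = sqrt(1 + 4q - 4q^2), q = r - floor(r) in [0,1):
//   phi(1+q) = (3-2q-s)/8, phi(q) = (3-2q+s)/8,
//   phi(1-q) = (1+2q+s)/8, phi(2-q) = (1+2q-s)/8.
static inline void axis_weights(double r, int &i0, double w[4]) {
  double fl = std::floor(r);
  double q = r - fl;
  i0 = (int)fl - 1;
  double s = std::sqrt(1.0 + 4.0 * q * (1.0 - q));
  w[0] = 0.125 * (3.0 - 2.0 * q - s);
  w[1] = 0.125 * (3.0 - 2.0 * q + s);
  w[2] = 0.125 * (1.0 + 2.0 * q + s);
  w[3] = 0.125 * (1.0 + 2.0 * q - s);
}

// [[Rcpp::export]]
Rcpp::List cpp_spread_structure(const arma::mat &x, const arma::imat &elems,
                                const arma::vec &V0, const arma::mat &dens,
                                int nx, int ny, int nz, double dx,
                                const arma::vec &origin) {
  cube fu(nx + 1, ny, nz, fill::zeros);
  cube fv(nx, ny + 1, nz, fill::zeros);
  cube fw(nx, ny, nz + 1, fill::zeros);
  double *pu = fu.memptr(), *pv = fv.memptr(), *pw = fw.memptr();
  const int sux = 1, suy = nx + 1, suz = (nx + 1) * ny;
  const int svx = 1, svy = nx, svz = nx * (ny + 1);
  const int swx = 1, swy = nx, swz = nx * ny;
  const double ox = origin(0), oy = origin(1), oz = origin(2);
  const double invh = 1.0 / dx, invh3 = invh * invh * invh;
  const uword m = elems.n_rows;
  const double half = 0.5 * dx;
  for (uword e = 0; e < m; ++e) {
    const int a0 = elems(e, 0), a1 = elems(e, 1), a2 = elems(e, 2),
              a3 = elems(e, 3);
    double X[4][3], Fd[4][3];
    const int ids[4] = {a0, a1, a2, a3};
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) {
        X[a][c] = x(ids[a], c);
        Fd[a][c] = dens(ids[a], c);
      }
    // max edge in the current configuration
    double em = 0.0;
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b) {
        double d0 = X[a][0] - X[b][0], d1 = X[a][1] - X[b][1],
               d2 = X[a][2] - X[b][2];
        double d = d0 * d0 + d1 * d1 + d2 * d2;
        if (d > em) em = d;
      }
    em = std::sqrt(em);
    int k = (int)std::ceil(em / half) - 1;
    if (k < 0) k = 0;
    const int npts = (k + 1) * (k + 2) * (k + 3) / 6;
    const double wq = V0(e) / npts * invh3;
    const double inv_k1 = 1.0 / (k + 1.0);
    for (int i = 0; i <= k; ++i)
      for (int j = 0; j <= k - i; ++j)
        for (int l = 0; l <= k - i - j; ++l) {
          const int r = k - i - j - l;
          const double b0 = (i + 0.25) * inv_k1, b1 = (j + 0.25) * inv_k1,
                       b2 = (l + 0.25) * inv_k1, b3 = (r + 0.25) * inv_k1;
          double px = b0 * X[0][0] + b1 * X[1][0] + b2 * X[2][0] + b3 * X[3][0];
          double py = b0 * X[0][1] + b1 * X[1][1] + b2 * X[2][1] + b3 * X[3][1];
          double pz = b0 * X[0][2] + b1 * X[1][2] + b2 * X[2][2] + b3 * X[3][2];
          double Fx = wq * (b0 * Fd[0][0] + b1 * Fd[1][0] + b2 * Fd[2][0] + b3 * Fd[3][0]);
          double Fy = wq * (b0 * Fd[0][1] + b1 * Fd[1][1] + b2 * Fd[2][1] + b3 * Fd[3][1]);
          double Fz = wq * (b0 * Fd[0][2] + b1 * Fd[1][2] + b2 * Fd[2][2] + b3 * Fd[3][2]);
          const double gx = (px - ox) * invh, gy = (py - oy) * invh,
                       gz = (pz - oz) * invh;
          int ix, iy, iz;
          double wxn[4], wyn[4], wzn[4], wxc[4], wyc[4], wzc[4];
          axis_weights(gx, ix, wxn);        // x-node offsets (u faces)
          axis_weights(gy, iy, wyn);        // y-node offsets (v faces)
          axis_weights(gz, iz, wzn);        // z-node offsets (w faces)
          int jx, jy, jz;
          axis_weights(gx - 0.5, jx, wxc);  // x-cell offsets
          axis_weights(gy - 0.5, jy, wyc);  // y-cell offsets
          axis_weights(gz - 0.5, jz, wzc);  // z-cell offsets
          if (ix < 0 || ix + 3 > nx || jx < 0 || jx + 3 >= nx ||
              iy < 0 || iy + 3 > ny || jy < 0 || jy + 3 >= ny ||
              iz < 0 || iz + 3 > nz || jz < 0 || jz + 3 >= nz)
            Rcpp::stop("structure point outside the fluid box (or within the delta-kernel support of its boundary)");
          // u: (node x, cell y, cell z)
          for (int c2 = 0; c2 < 4; ++c2) {
            const double wz2 = wzc[c2];
            for (int c1 = 0; c1 < 4; ++c1) {
              const double wyz = wyc[c1] * wz2;
              double *row = pu + (ix) * sux + (jy + c1) * suy + (jz + c2) * suz;
              row[0] += Fx * wxn[0] * wyz;
              row[1] += Fx * wxn[1] * wyz;
              row[2] += Fx * wxn[2] * wyz;
              row[3] += Fx * wxn[3] * wyz;
            }
          }
          // v: (cell x, node y, cell z)
          for (int c2 = 0; c2 < 4; ++c2) {
            const double wz2 = wzc[c2];
            for (int c1 = 0; c1 < 4; ++c1) {
              const double wyz = wyn[c1] * wz2;
              double *row = pv + (jx) * svx + (iy + c1) * svy + (jz + c2) * svz;
              row[0] += Fy * wxc[0] * wyz;
              row[1] += Fy * wxc[1] * wyz;
              row[2] += Fy * wxc[2] * wyz;
              row[3] += Fy * wxc[3] * wyz;
            }
          }
          // w: (cell x, cell y, node z)
          for (int c2 = 0; c2 < 4; ++c2) {
            const double wz2 = wzn[c2];
            for (int c1 = 0; c1 < 4; ++c1) {
              const double wyz = wyc[c1] * wz2;
              double *row = pw + (jx) * swx + (jy + c1) * swy + (iz + c2) * swz;
              row[0] += Fz * wxc[0] * wyz;
              row[1] += Fz * wxc[1] * wyz;
              row[2] += Fz * wxc[2] * wyz;
              row[3] += Fz * wxc[3] * wyz;
            }
          }
        }
  }
  return Rcpp::List::create(Rcpp::Named("u") = fu, Rcpp::Named("v") = fv,
                            Rcpp::Named("w") = fw);
}

// Consistent velocity interpolation for the FE structure: the exact
// transpose of cpp_spread_structure.  Velocities are delta-interpolated
// at the same element lattice points and projected onto the nodal basis
// with a lumped L2 projection,
//   Xdot_i = (1/Vlump_i) sum_q w_q phi_i(q) U(q),
// which makes the discrete Lagrangian-Eulerian power identity exact and
// keeps the coupled scheme from pumping energy.
// [[Rcpp::export]]
arma::mat cpp_interp_structure(const arma::mat &x, const arma::imat &elems,
                               const arma::vec &V0, const arma::vec &lumped,
                               const arma::cube &u, const arma::cube &v,
                               const arma::cube &w, int nx, int ny, int nz,
                               double dx, const arma::vec &origin) {
  mat out(x.n_rows, 3, fill::zeros);
  const double *pu = u.memptr(), *pv = v.memptr(), *pw = w.memptr();
  const int sux = 1, suy = nx + 1, suz = (nx + 1) * ny;
  const int svx = 1, svy = nx, svz = nx * (ny + 1);
  const int swx = 1, swy = nx, swz = nx * ny;
  const double ox = origin(0), oy = origin(1), oz = origin(2);
  const double invh = 1.0 / dx;
  const double half = 0.5 * dx;
  const uword m = elems.n_rows;
  for (uword e = 0; e < m; ++e) {
    const int ids[4] = {(int)elems(e, 0), (int)elems(e, 1), (int)elems(e, 2),
                        (int)elems(e, 3)};
    double X[4][3];
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) X[a][c] = x(ids[a], c);
    double em = 0.0;
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b) {
        double d0 = X[a][0] - X[b][0], d1 = X[a][1] - X[b][1],
               d2 = X[a][2] - X[b][2];
        double d = d0 * d0 + d1 * d1 + d2 * d2;
        if (d > em) em = d;
      }
    em = std::sqrt(em);
    int k = (int)std::ceil(em / half) - 1;
    if (k < 0) k = 0;
    const int npts = (k + 1) * (k + 2) * (k + 3) / 6;
    const double wq = V0(e) / npts;
    const double inv_k1 = 1.0 / (k + 1.0);
    for (int i = 0; i <= k; ++i)
      for (int j = 0; j <= k - i; ++j)
        for (int l = 0; l <= k - i - j; ++l) {
          const int r = k - i - j - l;
          const double b[4] = {(i + 0.25) * inv_k1, (j + 0.25) * inv_k1,
                               (l + 0.25) * inv_k1, (r + 0.25) * inv_k1};
          double px = b[0] * X[0][0] + b[1] * X[1][0] + b[2] * X[2][0] + b[3] * X[3][0];
          double py = b[0] * X[0][1] + b[1] * X[1][1] + b[2] * X[2][1] + b[3] * X[3][1];
          double pz = b[0] * X[0][2] + b[1] * X[1][2] + b[2] * X[2][2] + b[3] * X[3][2];
          const double gx = (px - ox) * invh, gy = (py - oy) * invh,
                       gz = (pz - oz) * invh;
          int ix, iy, iz, jx, jy, jz;
          double wxn[4], wyn[4], wzn[4], wxc[4], wyc[4], wzc[4];
          axis_weights(gx, ix, wxn);
          axis_weights(gy, iy, wyn);
          axis_weights(gz, iz, wzn);
          axis_weights(gx - 0.5, jx, wxc);
          axis_weights(gy - 0.5, jy, wyc);
          axis_weights(gz - 0.5, jz, wzc);
          if (ix < 0 || ix + 3 > nx || jx < 0 || jx + 3 >= nx ||
              iy < 0 || iy + 3 > ny || jy < 0 || jy + 3 >= ny ||
              iz < 0 || iz + 3 > nz || jz < 0 || jz + 3 >= nz)
            Rcpp::stop("structure point outside the fluid box (or within the delta-kernel support of its boundary)");
          double Ux = 0.0, Uy = 0.0, Uz = 0.0;
          for (int c2 = 0; c2 < 4; ++c2) {
            for (int c1 = 0; c1 < 4; ++c1) {
              const double wyzU = wyc[c1] * wzc[c2];
              const double *rowU = pu + ix * sux + (jy + c1) * suy + (jz + c2) * suz;
              Ux += wyzU * (rowU[0] * wxn[0] + rowU[1] * wxn[1] +
                            rowU[2] * wxn[2] + rowU[3] * wxn[3]);
              const double wyzV = wyn[c1] * wzc[c2];
              const double *rowV = pv + jx * svx + (iy + c1) * svy + (jz + c2) * svz;
              Uy += wyzV * (rowV[0] * wxc[0] + rowV[1] * wxc[1] +
                            rowV[2] * wxc[2] + rowV[3] * wxc[3]);
              const double wyzW = wyc[c1] * wzn[c2];
              const double *rowW = pw + jx * swx + (jy + c1) * swy + (iz + c2) * swz;
              Uz += wyzW * (rowW[0] * wxc[0] + rowW[1] * wxc[1] +
                            rowW[2] * wxc[2] + rowW[3] * wxc[3]);
            }
          }
          for (int a = 0; a < 4; ++a) {
            const double wa = wq * b[a];
            out(ids[a], 0) += wa * Ux;
            out(ids[a], 1) += wa * Uy;
            out(ids[a], 2) += wa * Uz;
          }
        }
  }
  for (uword i = 0; i < out.n_rows; ++i) {
    const double inv = 1.0 / lumped(i);
    out(i, 0) *= inv; out(i, 1) *= inv; out(i, 2) *= inv;
  }
  return out;
}
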