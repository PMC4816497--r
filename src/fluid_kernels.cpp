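// Incompressible Navier-Stokes on a staggered MAC grid: explicit
// two-stage (midpoint) advection-diffusion update followed by an exact
// discrete pressure projection.
//
// Boundary conditions on the box: either fully periodic (verification
// mode) or the physical combination of zero normal traction and zero
// tangential velocity on every face, which implies p = 0 on the
// boundary.  Discretely: tangential velocity ghosts are odd reflections
// (no tangential slip), normal velocity ghosts are even reflections
// (zero normal gradient, traction-free), and the pressure Poisson solve
// uses homogeneous Dirichlet ghosts.
//
// The Poisson problem is solved by geometric multigrid (red-black
// Gauss-Seidel smoothing, full-weighting restriction, piecewise-constant
// prolongation) to an absolute residual tolerance chosen so that the
// post-projection divergence meets the solver tolerance.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Grid {
  int nx, ny, nz;
  double dx;
  bool periodic;
};

inline int wrapi(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// --- ghosted access for velocity components ---------------------------
// comp: 0=u (normal x), 1=v (normal y), 2=w (normal z).
// Along the normal axis the face index runs 0..n (walls at 0 and n);
// ghosts reflect evenly about the wall faces (zero normal gradient).
// Along tangential axes the index runs 0..n-1 (centers); ghosts reflect
// oddly about the wall planes (zero tangential velocity).

inline double vel_at(const cube &f, const Grid &g, int comp, int i, int j,
                     int k) {
  if (g.periodic) {
    return f(comp == 0 ? wrapi(i, g.nx) : wrapi(i, g.nx),
             comp == 1 ? wrapi(j, g.ny) : wrapi(j, g.ny),
             comp == 2 ? wrapi(k, g.nz) : wrapi(k, g.nz));
  }
  double s = 1.0;
  if (comp == 0) {
    if (i < 0) i = -i;
    else if (i > g.nx) i = 2 * g.nx - i;
  } else {
    if (i < 0) { i = -1 - i; s = -s; }
    else if (i >= g.nx) { i = 2 * g.nx - 1 - i; s = -s; }
  }
  if (comp == 1) {
    if (j < 0) j = -j;
    else if (j > g.ny) j = 2 * g.ny - j;
  } else {
    if (j < 0) { j = -1 - j; s = -s; }
    else if (j >= g.ny) { j = 2 * g.ny - 1 - j; s = -s; }
  }
  if (comp == 2) {
    if (k < 0) k = -k;
    else if (k > g.nz) k = 2 * g.nz - k;
  } else {
    if (k < 0) { k = -1 - k; s = -s; }
    else if (k >= g.nz) { k = 2 * g.nz - 1 - k; s = -s; }
  }
  return s * f(i, j, k);
}

// Second-order upwind-biased first derivative of component field f along
// axis, at face index (i,j,k), advecting speed a.
inline double upwind2(const cube &f, const Grid &g, int comp, int i, int j,
                      int k, int axis, double a, double c0) {
  int di = axis == 0, dj = axis == 1, dk = axis == 2;
  if (a > 0) {
    double m1 = vel_at(f, g, comp, i - di, j - dj, k - dk);
    double m2 = vel_at(f, g, comp, i - 2 * di, j - 2 * dj, k - 2 * dk);
    return (3.0 * c0 - 4.0 * m1 + m2) / (2.0 * g.dx);
  }
  double p1 = vel_at(f, g, comp, i + di, j + dj, k + dk);
  double p2 = vel_at(f, g, comp, i + 2 * di, j + 2 * dj, k + 2 * dk);
  return (-3.0 * c0 + 4.0 * p1 - p2) / (2.0 * g.dx);
}

// slow path for one face (ghost-aware), used near the boundary shell
void rhs_face(const Grid &g, int comp, const cube &u, const cube &v,
              const cube &w, double nu, cube &out, int i, int j, int k);

// advection + diffusion right-hand side for one component
void rhs_component(const Grid &g, int comp, const cube &u, const cube &v,
                   const cube &w, double nu, cube &out) {
  const cube *selfp = comp == 0 ? &u : (comp == 1 ? &v : &w);
  const int mx = g.nx + (comp == 0), my = g.ny + (comp == 1),
            mz = g.nz + (comp == 2);
  const int ixmax = (g.periodic && comp == 0) ? g.nx : mx;
  const int iymax = (g.periodic && comp == 1) ? g.ny : my;
  const int izmax = (g.periodic && comp == 2) ? g.nz : mz;

  // interior fast path: all stencil reads in-range for self and the
  // cross components
  const double *A = selfp->memptr();
  const double *V = v.memptr(), *U = u.memptr(), *W = w.memptr();
  const int asx = 1, asy = mx, asz = mx * my;
  const int usy = g.nx + 1, usz = (g.nx + 1) * g.ny;
  const int vsy = g.nx, vsz = g.nx * (g.ny + 1);
  const int wsy = g.nx, wsz = g.nx * g.ny;
  const double invdx2 = 1.0 / (g.dx * g.dx), inv2dx = 0.5 / g.dx;
  double *O = out.memptr();
  const int ilo = 2, ihi = ixmax - 3, jlo = 2, jhi = iymax - 3,
            klo = 2, khi = izmax - 3;
  for (int k = klo; k <= khi; ++k)
    for (int j = jlo; j <= jhi; ++j) {
      for (int i = ilo; i <= ihi; ++i) {
        const int idx = i * asx + j * asy + k * asz;
        const double c0 = A[idx];
        double ax, ay, az;
        if (comp == 0) {
          const int vb = (i - 1) + j * vsy + k * vsz;
          ay = 0.25 * (V[vb] + V[vb + 1] + V[vb + vsy] + V[vb + 1 + vsy]);
          const int wb = (i - 1) + j * wsy + k * wsz;
          az = 0.25 * (W[wb] + W[wb + 1] + W[wb + wsz] + W[wb + 1 + wsz]);
          ax = c0;
        } else if (comp == 1) {
          const int ub = i + (j - 1) * usy + k * usz;
          ax = 0.25 * (U[ub] + U[ub + usy] + U[ub + 1] + U[ub + usy + 1]);
          const int wb = i + (j - 1) * wsy + k * wsz;
          az = 0.25 * (W[wb] + W[wb + wsy] + W[wb + wsz] + W[wb + wsy + wsz]);
          ay = c0;
        } else {
          const int ub = i + j * usy + (k - 1) * usz;
          ax = 0.25 * (U[ub] + U[ub + usz] + U[ub + 1] + U[ub + usz + 1]);
          const int vb = i + j * vsy + (k - 1) * vsz;
          ay = 0.25 * (V[vb] + V[vb + vsz] + V[vb + vsy] + V[vb + vsy + vsz]);
          az = c0;
        }
        double adv;
        adv = ax * ((ax > 0)
                      ? (3.0 * c0 - 4.0 * A[idx - asx] + A[idx - 2 * asx]) * inv2dx
                      : (-3.0 * c0 + 4.0 * A[idx + asx] - A[idx + 2 * asx]) * inv2dx);
        adv += ay * ((ay > 0)
                      ? (3.0 * c0 - 4.0 * A[idx - asy] + A[idx - 2 * asy]) * inv2dx
                      : (-3.0 * c0 + 4.0 * A[idx + asy] - A[idx + 2 * asy]) * inv2dx);
        adv += az * ((az > 0)
                      ? (3.0 * c0 - 4.0 * A[idx - asz] + A[idx - 2 * asz]) * inv2dx
                      : (-3.0 * c0 + 4.0 * A[idx + asz] - A[idx + 2 * asz]) * inv2dx);
        const double lap = (A[idx + asx] + A[idx - asx] + A[idx + asy] +
                            A[idx - asy] + A[idx + asz] + A[idx - asz] -
                            6.0 * c0) * invdx2;
        O[idx] = -adv + nu * lap;
      }
    }
  // boundary shell via the ghost-aware path
  for (int k = 0; k < izmax; ++k)
    for (int j = 0; j < iymax; ++j)
      for (int i = 0; i < ixmax; ++i) {
        if (i >= ilo && i <= ihi && j >= jlo && j <= jhi && k >= klo && k <= khi)
          continue;
        rhs_face(g, comp, u, v, w, nu, out, i, j, k);
      }
}

void rhs_face(const Grid &g, int comp, const cube &u, const cube &v,
              const cube &w, double nu, cube &out, int i, int j, int k) {
  const cube *self = comp == 0 ? &u : (comp == 1 ? &v : &w);
  {
      {
        double c0 = (*self)(i, j, k);
        // advecting velocities at this face
        double ax, ay, az;
        if (comp == 0) {
          ax = c0;
          ay = 0.25 * (vel_at(v, g, 1, i - 1, j, k) + vel_at(v, g, 1, i, j, k) +
                       vel_at(v, g, 1, i - 1, j + 1, k) + vel_at(v, g, 1, i, j + 1, k));
          az = 0.25 * (vel_at(w, g, 2, i - 1, j, k) + vel_at(w, g, 2, i, j, k) +
                       vel_at(w, g, 2, i - 1, j, k + 1) + vel_at(w, g, 2, i, j, k + 1));
        } else if (comp == 1) {
          ax = 0.25 * (vel_at(u, g, 0, i, j - 1, k) + vel_at(u, g, 0, i, j, k) +
                       vel_at(u, g, 0, i + 1, j - 1, k) + vel_at(u, g, 0, i + 1, j, k));
          ay = c0;
          az = 0.25 * (vel_at(w, g, 2, i, j - 1, k) + vel_at(w, g, 2, i, j, k) +
                       vel_at(w, g, 2, i, j - 1, k + 1) + vel_at(w, g, 2, i, j, k + 1));
        } else {
          ax = 0.25 * (vel_at(u, g, 0, i, j, k - 1) + vel_at(u, g, 0, i, j, k) +
                       vel_at(u, g, 0, i + 1, j, k - 1) + vel_at(u, g, 0, i + 1, j, k));
          ay = 0.25 * (vel_at(v, g, 1, i, j, k - 1) + vel_at(v, g, 1, i, j, k) +
                       vel_at(v, g, 1, i, j + 1, k - 1) + vel_at(v, g, 1, i, j + 1, k));
          az = c0;
        }
        double adv = ax * upwind2(*self, g, comp, i, j, k, 0, ax, c0) +
                     ay * upwind2(*self, g, comp, i, j, k, 1, ay, c0) +
                     az * upwind2(*self, g, comp, i, j, k, 2, az, c0);
        double lap =
            (vel_at(*self, g, comp, i + 1, j, k) + vel_at(*self, g, comp, i - 1, j, k) +
             vel_at(*self, g, comp, i, j + 1, k) + vel_at(*self, g, comp, i, j - 1, k) +
             vel_at(*self, g, comp, i, j, k + 1) + vel_at(*self, g, comp, i, j, k - 1) -
             6.0 * c0) / (g.dx * g.dx);
        out(i, j, k) = -adv + nu * lap;
      }
  }
}

void sync_planes(const Grid &g, cube &u, cube &v, cube &w) {
  if (!g.periodic) return;
  for (int j = 0; j < g.ny; ++j)
    for (int k = 0; k < g.nz; ++k) u(g.nx, j, k) = u(0, j, k);
  for (int i = 0; i < g.nx; ++i)
    for (int k = 0; k < g.nz; ++k) v(i, g.ny, k) = v(i, 0, k);
  for (int i = 0; i < g.nx; ++i)
    for (int j = 0; j < g.ny; ++j) w(i, j, g.nz) = w(i, j, 0);
}

// --- Poisson multigrid -------------------------------------------------

inline double phi_at(const cube &phi, const Grid &g, int i, int j, int k) {
  if (g.periodic)
    return phi(wrapi(i, g.nx), wrapi(j, g.ny), wrapi(k, g.nz));
  double s = 1.0;
  if (i < 0) { i = -1 - i; s = -s; }
  else if (i >= g.nx) { i = 2 * g.nx - 1 - i; s = -s; }
  if (j < 0) { j = -1 - j; s = -s; }
  else if (j >= g.ny) { j = 2 * g.ny - 1 - j; s = -s; }
  if (k < 0) { k = -1 - k; s = -s; }
  else if (k >= g.nz) { k = 2 * g.nz - 1 - k; s = -s; }
  return s * phi(i, j, k);
}

void gs_sweep(const Grid &g, cube &phi, const cube &rhs) {
  const double h2 = g.dx * g.dx;
  for (int color = 0; color < 2; ++color)
    for (int k = 0; k < g.nz; ++k)
      for (int j = 0; j < g.ny; ++j)
        for (int i = 0; i < g.nx; ++i) {
          if (((i + j + k) & 1) != color) continue;
          double S = 0.0;
          double diag = 6.0;
          if (g.periodic) {
            S = phi(wrapi(i + 1, g.nx), j, k) + phi(wrapi(i - 1, g.nx), j, k) +
                phi(i, wrapi(j + 1, g.ny), k) + phi(i, wrapi(j - 1, g.ny), k) +
                phi(i, j, wrapi(k + 1, g.nz)) + phi(i, j, wrapi(k - 1, g.nz));
          } else {
            if (i + 1 < g.nx) S += phi(i + 1, j, k); else diag += 1.0;
            if (i - 1 >= 0) S += phi(i - 1, j, k); else diag += 1.0;
            if (j + 1 < g.ny) S += phi(i, j + 1, k); else diag += 1.0;
            if (j - 1 >= 0) S += phi(i, j - 1, k); else diag += 1.0;
            if (k + 1 < g.nz) S += phi(i, j, k + 1); else diag += 1.0;
            if (k - 1 >= 0) S += phi(i, j, k - 1); else diag += 1.0;
          }
          phi(i, j, k) = (S - h2 * rhs(i, j, k)) / diag;
        }
}

void residual(const Grid &g, const cube &phi, const cube &rhs, cube &res) {
  const double h2 = g.dx * g.dx;
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        double lap = phi_at(phi, g, i + 1, j, k) + phi_at(phi, g, i - 1, j, k) +
                     phi_at(phi, g, i, j + 1, k) + phi_at(phi, g, i, j - 1, k) +
                     phi_at(phi, g, i, j, k + 1) + phi_at(phi, g, i, j, k - 1) -
                     6.0 * phi(i, j, k);
        res(i, j, k) = rhs(i, j, k) - lap / h2;
      }
}

void vcycle(const Grid &g, cube &phi, const cube &rhs) {
  bool can_coarsen = (g.nx % 2 == 0) && (g.ny % 2 == 0) && (g.nz % 2 == 0) &&
                     g.nx >= 4 && g.ny >= 4 && g.nz >= 4;
  if (!can_coarsen) {
    for (int s = 0; s < 200; ++s) gs_sweep(g, phi, rhs);
    return;
  }
  for (int s = 0; s < 3; ++s) gs_sweep(g, phi, rhs);
  cube res(g.nx, g.ny, g.nz);
  residual(g, phi, rhs, res);
  Grid gc = g;
  gc.nx = g.nx / 2; gc.ny = g.ny / 2; gc.nz = g.nz / 2; gc.dx = 2.0 * g.dx;
  cube rc(gc.nx, gc.ny, gc.nz);
  for (int k = 0; k < gc.nz; ++k)
    for (int j = 0; j < gc.ny; ++j)
      for (int i = 0; i < gc.nx; ++i) {
        double sum = 0.0;
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2; ++b)
            for (int c = 0; c < 2; ++c)
              sum += res(2 * i + a, 2 * j + b, 2 * k + c);
        rc(i, j, k) = sum / 8.0;
      }
  cube ec(gc.nx, gc.ny, gc.nz, fill::zeros);
  vcycle(gc, ec, rc);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i)
        phi(i, j, k) += ec(i / 2, j / 2, k / 2);
  for (int s = 0; s < 3; ++s) gs_sweep(g, phi, rhs);
}

// Solve lap(phi) = rhs to max-norm residual <= atol.  Returns cycles
// used, or stops with an error if the solver stalls.
int poisson_solve(const Grid &g, cube &phi, cube rhs, double atol,
                  int maxcyc) {
  if (g.periodic) rhs -= accu(rhs) / rhs.n_elem;
  cube res(g.nx, g.ny, g.nz);
  for (int cyc = 0; cyc < maxcyc; ++cyc) {
    residual(g, phi, rhs, res);
    double r = abs(res).max();
    if (r <= atol) {
      if (g.periodic) phi -= accu(phi) / phi.n_elem;
      return cyc;
    }
    vcycle(g, phi, rhs);
    if (g.periodic) phi -= accu(phi) / phi.n_elem;
  }
  residual(g, phi, rhs, res);
  if (abs(res).max() > atol)
    Rcpp::stop("pressure Poisson solver did not reach the requested tolerance");
  return maxcyc;
}

void mac_div(const Grid &g, const cube &u, const cube &v, const cube &w,
             cube &div) {
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i)
        div(i, j, k) = (u(i + 1, j, k) - u(i, j, k) + v(i, j + 1, k) -
                        v(i, j, k) + w(i, j, k + 1) - w(i, j, k)) / g.dx;
}

// subtract (dt/rho) grad phi from the face velocities, using the same
// ghost conventions as the Poisson operator so the projection is exact.
void apply_grad(const Grid &g, const cube &phi, double scale, cube &u,
                cube &v, cube &w) {
  int iu = g.periodic ? g.nx : g.nx + 1;
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < iu; ++i)
        u(i, j, k) -= scale * (phi_at(phi, g, i, j, k) - phi_at(phi, g, i - 1, j, k)) / g.dx;
  int jv = g.periodic ? g.ny : g.ny + 1;
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < jv; ++j)
      for (int i = 0; i < g.nx; ++i)
        v(i, j, k) -= scale * (phi_at(phi, g, i, j, k) - phi_at(phi, g, i, j - 1, k)) / g.dx;
  int kw = g.periodic ? g.nz : g.nz + 1;
  for (int k = 0; k < kw; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i)
        w(i, j, k) -= scale * (phi_at(phi, g, i, j, k) - phi_at(phi, g, i, j, k - 1)) / g.dx;
}

} // namespace

// [[Rcpp::export]]
arma::cube cpp_mac_divergence(const arma::cube &u, const arma::cube &v,
                              const arma::cube &w, double dx, bool periodic) {
  Grid g;
  g.nx = v.n_rows; g.ny = u.n_cols; g.nz = u.n_slices;
  g.dx = dx; g.periodic = periodic;
  cube div(g.nx, g.ny, g.nz);
  mac_div(g, u, v, w, div);
  return div;
}

// [[Rcpp::export]]
Rcpp::List cpp_poisson(const arma::cube &rhs, double dx, bool periodic,
                       double atol, int maxcyc,
                       Rcpp::Nullable<Rcpp::NumericVector> guess = R_NilValue) {
  Grid g;
  g.nx = rhs.n_rows; g.ny = rhs.n_cols; g.nz = rhs.n_slices;
  g.dx = dx; g.periodic = periodic;
  cube phi(g.nx, g.ny, g.nz, fill::zeros);
  if (guess.isNotNull()) {
    Rcpp::NumericVector gv(guess);
    if ((int)gv.size() == (int)phi.n_elem)
      std::copy(gv.begin(), gv.end(), phi.memptr());
  }
  int cyc = poisson_solve(g, phi, rhs, atol, maxcyc);
  return Rcpp::List::create(Rcpp::Named("phi") = phi,
                            Rcpp::Named("cycles") = cyc);
}

// Project a face velocity field to the discretely divergence-free space.
// [[Rcpp::export]]
Rcpp::List cpp_mac_project(const arma::cube &u0, const arma::cube &v0,
                           const arma::cube &w0, double dx, double dt,
                           double rho, bool periodic, double div_tol,
                           int maxcyc,
                           Rcpp::Nullable<Rcpp::NumericVector> guess = R_NilValue) {
  Grid g;
  g.nx = v0.n_rows; g.ny = u0.n_cols; g.nz = u0.n_slices;
  g.dx = dx; g.periodic = periodic;
  cube u = u0, v = v0, w = w0;
  cube div(g.nx, g.ny, g.nz);
  mac_div(g, u, v, w, div);
  cube rhs = (rho / dt) * div;
  cube phi(g.nx, g.ny, g.nz, fill::zeros);
  if (guess.isNotNull()) {
    Rcpp::NumericVector gv(guess);
    if ((int)gv.size() == (int)phi.n_elem)
      std::copy(gv.begin(), gv.end(), phi.memptr());
  }
  int cyc = poisson_solve(g, phi, rhs, div_tol * rho / dt, maxcyc);
  apply_grad(g, phi, dt / rho, u, v, w);
  sync_planes(g, u, v, w);
  mac_div(g, u, v, w, div);
  return Rcpp::List::create(
      Rcpp::Named("u") = u, Rcpp::Named("v") = v, Rcpp::Named("w") = w,
      Rcpp::Named("p") = phi, Rcpp::Named("max_div") = abs(div).max(),
      Rcpp::Named("cycles") = cyc);
}

// One explicit two-stage (midpoint) Navier-Stokes step with body force f
// (force per unit volume on the faces) and pressure projection.
// [[Rcpp::export]]
Rcpp::List cpp_ns_step(const arma::cube &u0, const arma::cube &v0,
                       const arma::cube &w0, const arma::cube &fu,
                       const arma::cube &fv, const arma::cube &fw, double dt,
                       double rho, double mu, double dx, bool periodic,
                       double div_tol, int maxcyc,
                       Rcpp::Nullable<Rcpp::NumericVector> guess = R_NilValue) {
  Grid g;
  g.nx = v0.n_rows; g.ny = u0.n_cols; g.nz = u0.n_slices;
  g.dx = dx; g.periodic = periodic;
  const double nu = mu / rho;

  double umax = std::max({abs(u0).max(), abs(v0).max(), abs(w0).max()});
  if (umax * dt / dx > 1.0)
    Rcpp::stop("time step violates the advective CFL limit (max|u| dt / dx = %g > 1)",
               umax * dt / dx);
  if (6.0 * nu * dt / (dx * dx) > 1.0)
    Rcpp::stop("time step violates the viscous stability limit (6 nu dt / dx^2 = %g > 1)",
               6.0 * nu * dt / (dx * dx));

  cube ru(size(u0)), rv(size(v0)), rw(size(w0));
  ru.zeros(); rv.zeros(); rw.zeros();

  // stage 1: forward Euler predictor
  rhs_component(g, 0, u0, v0, w0, nu, ru);
  rhs_component(g, 1, u0, v0, w0, nu, rv);
  rhs_component(g, 2, u0, v0, w0, nu, rw);
  cube u1 = u0 + dt * (ru + fu / rho);
  cube v1 = v0 + dt * (rv + fv / rho);
  cube w1 = w0 + dt * (rw + fw / rho);
  sync_planes(g, u1, v1, w1);
  {
    cube div(g.nx, g.ny, g.nz);
    mac_div(g, u1, v1, w1, div);
    cube rhs = (rho / dt) * div;
    cube phi(g.nx, g.ny, g.nz, fill::zeros);
    if (guess.isNotNull()) {
      Rcpp::NumericVector gv(guess);
      if ((int)gv.size() == (int)phi.n_elem)
        std::copy(gv.begin(), gv.end(), phi.memptr());
    }
    poisson_solve(g, phi, rhs, div_tol * rho / dt, maxcyc);
    apply_grad(g, phi, dt / rho, u1, v1, w1);
    sync_planes(g, u1, v1, w1);
  }

  // stage 2: midpoint corrector
  cube um = 0.5 * (u0 + u1), vm = 0.5 * (v0 + v1), wm = 0.5 * (w0 + w1);
  rhs_component(g, 0, um, vm, wm, nu, ru);
  rhs_component(g, 1, um, vm, wm, nu, rv);
  rhs_component(g, 2, um, vm, wm, nu, rw);
  cube u2 = u0 + dt * (ru + fu / rho);
  cube v2 = v0 + dt * (rv + fv / rho);
  cube w2 = w0 + dt * (rw + fw / rho);
  sync_planes(g, u2, v2, w2);
  cube phi(g.nx, g.ny, g.nz, fill::zeros);
  if (guess.isNotNull()) {
    Rcpp::NumericVector gv(guess);
    if ((int)gv.size() == (int)phi.n_elem)
      std::copy(gv.begin(), gv.end(), phi.memptr());
  }
  int cyc;
  double maxdiv;
  {
    cube div(g.nx, g.ny, g.nz);
    mac_div(g, u2, v2, w2, div);
    cube rhs = (rho / dt) * div;
    cyc = poisson_solve(g, phi, rhs, div_tol * rho / dt, maxcyc);
    apply_grad(g, phi, dt / rho, u2, v2, w2);
    sync_planes(g, u2, v2, w2);
    mac_div(g, u2, v2, w2, div);
    maxdiv = abs(div).max();
  }
  return Rcpp::List::create(
      Rcpp::Named("u") = u2, Rcpp::Named("v") = v2, Rcpp::Named("w") = w2,
      Rcpp::Named("p") = phi, Rcpp::Named("max_div") = maxdiv,
      Rcpp::Named("cycles") = cyc, Rcpp::Named("cfl") = umax * dt / dx);
}
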