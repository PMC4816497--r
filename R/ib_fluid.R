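#' Staggered MAC grid
#'
#' Allocates the Eulerian state: face-centred velocity components `u`,
#' `v`, `w` and the cell-centred pressure over a box with isotropic
#' spacing. The default desk-scale grid is 32 x 32 x 40 cells at
#' `dx = 15/32` cm; the cluster preset of [default_config()] uses
#' 96 x 96 x 128 at `dx = 0.156` cm.
#'
#' @param n integer cell counts `c(nx, ny, nz)`.
#' @param dx grid spacing (cm), identical in all directions.
#' @param origin lower box corner (cm); default centres the box at the
#'   origin.
#' @param rho fluid/solid mass density (g/ml).
#' @param mu dynamic viscosity (g/(cm s) = poise). The default 0.04
#'   corresponds to 4 cP, physiological blood viscosity.
#' @param periodic logical; periodic box (solver verification mode) or
#'   the physical zero-normal-traction / zero-tangential-velocity box.
#' @return An object of class `staggered_grid`.
#' @export
staggered_grid <- function(n = c(32, 32, 40), dx = 15 / 32, origin = NULL,
                           rho = 1.0, mu = 0.04, periodic = FALSE) {
  n <- as.integer(n)
  stopifnot(length(n) == 3, all(n >= 4), dx > 0, rho > 0, mu >= 0)
  if (is.null(origin)) origin <- -n * dx / 2
  g <- list(n = n, dx = dx, origin = as.numeric(origin), box = n * dx,
            rho = rho, mu = mu, periodic = periodic,
            u = array(0, c(n[1] + 1, n[2], n[3])),
            v = array(0, c(n[1], n[2] + 1, n[3])),
            w = array(0, c(n[1], n[2], n[3] + 1)),
            p = array(0, n))
  class(g) <- "staggered_grid"
  g
}

#' @export
print.staggered_grid <- function(x, ...) {
  cat(sprintf("MAC grid %d x %d x %d, dx = %.4g cm, box %.3g x %.3g x %.3g cm%s\n",
              x$n[1], x$n[2], x$n[3], x$dx, x$box[1], x$box[2], x$box[3],
              if (x$periodic) " (periodic)" else ""))
  invisible(x)
}

#' Four-point regularized delta function
#'
#' The standard immersed-boundary four-point kernel
#' \eqn{\delta_4(r)}: even, continuous, supported on `|r| < 2`, and
#' satisfying the discrete partition-of-unity and first-moment
#' conditions \eqn{\sum_j \delta_4(r-j) = 1},
#' \eqn{\sum_j (r-j)\,\delta_4(r-j) = 0} for every real `r`.
#'
#' @param r grid-scaled offsets (numeric vector).
#' @return Kernel weights.
#' @examples
#' delta4(0)      # 0.5
#' delta4(2.5)    # 0
#' @export
delta4 <- function(r) as.numeric(cpp_delta4(as.numeric(r)))

#' Spread Lagrangian forces to the Eulerian grid
#'
#' Discretization of the force-spreading transform: for point forces
#' `F_q` (already quadrature-weighted, in dyne) at positions `X_q`,
#' each MAC face receives
#' \eqn{f = \sum_q F_q\, \delta_h(x - X_q)} (force per unit volume).
#' The total spread force times the cell volume equals the total input
#' force componentwise (discrete conservation).
#'
#' @param grid a [staggered_grid()].
#' @param points q x 3 positions (cm).
#' @param forces q x 3 forces (dyne), already multiplied by quadrature
#'   weights.
#' @return A list of face arrays `u`, `v`, `w` (force density).
#' @export
spread <- function(grid, points, forces) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (is.null(dim(forces))) forces <- matrix(forces, ncol = 3)
  cpp_spread_mac(points, forces, grid$n[1], grid$n[2], grid$n[3], grid$dx,
                 grid$origin, grid$periodic)
}

#' Interpolate grid velocity to Lagrangian points
#'
#' Adjoint of [spread()]: \eqn{U(q) = \sum_x u(x)\,\delta_h(x -
#' X_q)\,\Delta x^3}, evaluated per velocity component at its own face
#' positions.
#'
#' @param grid a [staggered_grid()].
#' @param points q x 3 positions (cm).
#' @return q x 3 velocities (cm/s).
#' @export
interpolate_velocity <- function(grid, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  cpp_interp_mac(grid$u, grid$v, grid$w, points, grid$n[1], grid$n[2],
                 grid$n[3], grid$dx, grid$origin, grid$periodic)
}

#' One Navier-Stokes time step
#'
#' Advances the Eulerian velocity by an explicit two-stage (midpoint)
#' advection-diffusion update with the body force `f`, followed by a
#' pressure projection enforcing the discrete divergence-free
#' constraint to `div_tol`. Errors if `dt` violates the advective CFL
#' or viscous stability limit, naming the limiting constraint.
#'
#' @param grid a [staggered_grid()].
#' @param f body-force face arrays as returned by [spread()] (or
#'   `NULL` for no force).
#' @param dt time step (s).
#' @param div_tol post-projection divergence tolerance (1/s).
#' @param maxcyc maximum multigrid cycles.
#' @return The updated grid (with `p` the projection potential) plus
#'   diagnostics `max_div`, `cycles`, `cfl`.
#' @export
ns_step <- function(grid, f = NULL, dt, div_tol = 1e-9, maxcyc = 100) {
  if (is.null(f)) {
    f <- list(u = array(0, dim(grid$u)), v = array(0, dim(grid$v)),
              w = array(0, dim(grid$w)))
  }
  out <- cpp_ns_step(grid$u, grid$v, grid$w, f$u, f$v, f$w, dt, grid$rho,
                     grid$mu, grid$dx, grid$periodic, div_tol, maxcyc,
                     as.numeric(grid$p))
  grid$u <- out$u; grid$v <- out$v; grid$w <- out$w; grid$p <- out$p
  grid$max_div <- out$max_div; grid$cycles <- out$cycles; grid$cfl <- out$cfl
  grid
}

#' Divergence of the MAC velocity field
#'
#' @param grid a [staggered_grid()].
#' @return nx x ny x nz array of cell divergences (1/s).
#' @export
mac_divergence <- function(grid) {
  cpp_mac_divergence(grid$u, grid$v, grid$w, grid$dx, grid$periodic)
}

#' Advance structure nodes with interpolated velocities
#'
#' Explicit update \eqn{X \leftarrow X + \Delta t\, U} of the no-slip
#' condition that the structure moves with the local fluid velocity.
#'
#' @param x n x 3 nodal positions (cm).
#' @param U n x 3 velocities (cm/s).
#' @param dt time step (s).
#' @return Updated positions.
#' @export
advance_structure <- function(x, U, dt) x + dt * U
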