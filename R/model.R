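#' Assemble a simulation-ready LV model
#'
#' Bundles the Lagrangian anatomy (mesh + fibre frames + optional
#' infarct field), the constitutive parameter sets, the Eulerian grid
#' and the numerical settings into one object consumed by
#' [run_diastole()] and [run_systole()].
#'
#' The Eulerian box is centred on the LV (laterally at the origin,
#' axially on the mesh midpoint); an error is raised if the structure
#' would start within the delta-kernel support of the box boundary.
#'
#' @param mesh an [make_idealized_lv()] mesh (or compatible).
#' @param passive a [passive_params()] set.
#' @param active an [active_params()] set.
#' @param infarct optional [make_synthetic_infarct()] field; `NULL` for
#'   a healthy ventricle.
#' @param T_scale contractility scale (dimensionless).
#' @param grid_n Eulerian cell counts.
#' @param dx Eulerian grid spacing (cm).
#' @param rho,mu fluid/solid density (g/ml) and viscosity (poise).
#' @param kappa_basal basal penalty stiffness density
#'   (dyne/cm^3 per cm; a numerical tether, see
#'   [basal_constraint_force()]).
#' @param div_tol projection divergence tolerance.
#' @return An object of class `lv_model`.
#' @export
lv_model <- function(mesh, passive = passive_params(),
                     active = active_params(), infarct = NULL,
                     T_scale = 3.0, grid_n = c(32, 32, 40), dx = 15 / 32,
                     rho = 1.0, mu = 0.04, kappa_basal = 2e6,
                     div_tol = 1e-9) {
  pre <- fe_precompute(mesh)
  zmid <- (mesh$base_z + mesh$apex_z) / 2
  origin <- c(-grid_n[1] * dx / 2, -grid_n[2] * dx / 2,
              zmid - grid_n[3] * dx / 2)
  grid <- staggered_grid(grid_n, dx, origin = origin, rho = rho, mu = mu)
  margin <- 3 * dx
  lo <- apply(mesh$nodes, 2, min); hi <- apply(mesh$nodes, 2, max)
  if (any(lo < grid$origin + margin) || any(hi > grid$origin + grid$box - margin))
    stop("LV mesh does not fit in the fluid box with the required margin")
  M_elem <- if (is.null(infarct)) rep(0, nrow(mesh$elems)) else infarct$M_elem
  model <- list(mesh = mesh, pre = pre, passive = passive, active = active,
                infarct = infarct, M_elem = M_elem, T_scale = T_scale,
                grid = grid, kappa_basal = kappa_basal,
                basal_nodes = basal_node_ids(mesh), div_tol = div_tol)
  class(model) <- "lv_model"
  model
}

#' @export
print.lv_model <- function(x, ...) {
  cat("IB/FE LV model\n")
  print(x$mesh)
  print(x$grid)
  cat(sprintf("  T_scale = %.2f; infarct: %s; basal penalty %.2g\n", x$T_scale,
              if (is.null(x$infarct)) "none" else
                sprintf("%.0f%% of wall", 100 * x$infarct$fraction),
              x$kappa_basal))
  invisible(x)
}

#' Initial coupled state
#'
#' @param model an [lv_model()].
#' @return A list with nodal positions `x`, the fluid `grid`, active
#'   states, the previous fibre stretch (for the stretch-rate backward
#'   difference) and the clock `t`.
#' @keywords internal
#' @export
lv_state_init <- function(model) {
  m <- nrow(model$mesh$elems)
  list(x = model$mesh$nodes, grid = model$grid,
       act = active_state_init(m), lambda_prev = rep(1, m), t = 0)
}

# One coupled IB time step (midpoint scheme): structure positions are
# advanced to the half step with the beginning-of-step velocity, all
# Lagrangian forces are evaluated and spread from the midpoint
# configuration, the fluid is advanced through the full step, and the
# structure completes the step with the time-averaged velocity.
lv_step <- function(model, state, dt, p_endo, ca, damping = 0) {
  mesh <- model$mesh; pre <- model$pre; grid <- state$grid
  U0 <- structure_velocity(model, grid, state$x)
  xh <- state$x + 0.5 * dt * U0

  F <- cpp_tet_defgrad(xh, mesh$elems - 1L, pre$gradN)
  Jd <- cpp_defgrad_det(F)
  if (any(Jd <= 0)) {
    stop(sprintf("element inversion (min det F = %.3g at element %d, t = %.4f s)",
                 min(Jd), which.min(Jd), state$t))
  }
  lam <- cpp_fibre_stretch(F, mesh$f0)
  dlam <- (lam - state$lambda_prev) / dt
  act <- step_active_state(state$act, lam, dlam, ca, dt,
                           params = model$active, T_scale = model$T_scale,
                           M = model$M_elem)
  T_cgs <- kpa_to_barye(act$T)
  P <- cpp_pk1_bulk(F, mesh$f0, mesh$s0, model$passive$cgs, model$M_elem, T_cgs)

  G <- cpp_fe_internal_force(mesh$elems - 1L, pre$gradN, pre$V0, P,
                             nrow(mesh$nodes))
  G <- G + cpp_pressure_force(xh, mesh$faces$endo - 1L,
                              mmhg_to_barye(p_endo), nrow(mesh$nodes))
  G <- G + basal_constraint_force(mesh, xh, model$kappa_basal, pre,
                                  model$basal_nodes)
  dens <- G / pre$lumped

  f <- cpp_spread_structure(xh, mesh$elems - 1L, pre$V0, dens, grid$n[1],
                            grid$n[2], grid$n[3], grid$dx, grid$origin)

  gridn <- ns_step(grid, f, dt, div_tol = model$div_tol)
  if (damping > 0) {
    # quasi-static relaxation: exponential bulk friction, divergence-
    # preserving; accelerates convergence to the (velocity-free) static
    # equilibrium the loading protocols seek without changing it
    fac <- exp(-damping * dt)
    gridn$u <- gridn$u * fac
    gridn$v <- gridn$v * fac
    gridn$w <- gridn$w * fac
  }
  Uh0 <- structure_velocity(model, grid, xh)
  Uh1 <- structure_velocity(model, gridn, xh)
  state$x <- state$x + dt * 0.5 * (Uh0 + Uh1)
  state$grid <- gridn
  state$act <- act$states
  state$T_elem <- act$T
  state$lambda_prev <- lam
  state$t <- state$t + dt
  state$max_J_dev <- max(abs(Jd - 1))
  state
}

# Nodal structure velocity: delta interpolation at the element
# quadrature points followed by a lumped L2 projection onto the FE
# basis; the exact transpose of the force spreading, so the discrete
# Lagrangian-Eulerian power identity holds.
structure_velocity <- function(model, grid, x) {
  cpp_interp_structure(x, model$mesh$elems - 1L, model$pre$V0,
                       model$pre$lumped, grid$u, grid$v, grid$w, grid$n[1],
                       grid$n[2], grid$n[3], grid$dx, grid$origin)
}
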