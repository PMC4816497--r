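#' Active contraction model parameters
#'
#' Parameters of the length- and velocity-dependent active tension
#' model used for excitation-contraction coupling. Tension is generated
#' by a three-stage chain: (i) calcium binds troponin C with a
#' tension-dependent unbinding rate, (ii) a tropomyosin gate `z` opens
#' with Hill-type cooperativity toward a length-dependent half
#' activation, and (iii) fading-memory crossbridge variables `Q1..Q3`
#' modulate tension under changing fibre stretch. At saturating calcium
#' and fixed stretch the steady tension is exactly
#' \deqn{T = T_{ref}\,(1 + \beta_0(\lambda_f - 1)),}
#' because the gate is normalized by its own fully loaded steady state
#' `z_max(lambda)`.
#'
#' The generated tension is multiplied by the dimensionless
#' contractility scale `T_scale` (the single parameter adjusted when
#' matching end-systolic volumes) and, in infarcted tissue, by the
#' contractility factor \eqn{1 - M}.
#'
#' @param T_ref reference isometric tension at the resting sarcomere
#'   length (kPa). The default 56.2 kPa corresponds to a healthy
#'   ventricle with `T_scale = 3`.
#' @param lambda_min,lambda_max validity range of the fibre stretch
#'   (sarcomere length) dependence; `lambda_max` is the stretch at the
#'   maximum sarcomere length.
#' @param ... overrides for the kinetic constants (see Details).
#' @details Kinetic constants and defaults: `k_on` = 100 /uM/s,
#'   `k_off_ref` = 200 /s, `gamma_trpn` = 2, `ca_trpn_max` = 70 uM,
#'   `ca50_ref` = 1.05 uM, `n_hill` = 3, `alpha0` = 8 /s, `alpha_r1` =
#'   2 /s, `alpha_r2` = 1.75 /s, `K_Z` = 0.15, `n_r` = 3, `beta0` = 4.9,
#'   `beta1` = -4, `a_xb` = 0.35, `A` = (-29, 138, 129),
#'   `alpha_q` = (30, 130, 625) /s.
#' @return An object of class `active_params` with `$vec`, the packed
#'   parameter vector used by the kernels.
#' @export
active_params <- function(T_ref = 56.2, lambda_min = 0.8, lambda_max = 1.15,
                          ...) {
  p <- list(T_ref = T_ref, k_on = 100, k_off_ref = 200, gamma_trpn = 2,
            ca_trpn_max = 70, ca50_ref = 1.05, n_hill = 3, alpha0 = 8,
            alpha_r1 = 2, alpha_r2 = 1.75, K_Z = 0.15, n_r = 3,
            beta0 = 4.9, beta1 = -4, a_xb = 0.35,
            A = c(-29, 138, 129), alpha_q = c(30, 130, 625),
            lambda_min = lambda_min, lambda_max = lambda_max)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown active-model parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  if (p$T_ref <= 0) stop("T_ref must be positive")
  if (p$lambda_min >= p$lambda_max) stop("lambda_min must be < lambda_max")
  p$vec <- c(p$T_ref, p$k_on, p$k_off_ref, p$gamma_trpn, p$ca_trpn_max,
             p$ca50_ref, p$n_hill, p$alpha0, p$alpha_r1, p$alpha_r2,
             p$K_Z, p$n_r, p$beta0, p$beta1, p$a_xb, p$A, p$alpha_q,
             p$lambda_min, p$lambda_max)
  class(p) <- "active_params"
  p
}

#' Prescribed intracellular calcium transient
#'
#' The spatially uniform analytic calcium waveform used to drive
#' contraction,
#' \deqn{[Ca]_i(t) = Ca_0 + (Ca_{max} - Ca_0)\,\frac{t - t_0}{\tau}\,
#'   e^{1 - (t - t_0)/\tau}, \quad t \ge t_0,}
#' a single-peaked pulse that starts at the baseline `ca_base`, peaks at
#' `ca_peak` exactly `tau` after the activation onset `t_act`, and
#' relaxes back to baseline.
#'
#' @param ca_base diastolic baseline concentration (uM).
#' @param ca_peak peak systolic concentration (uM).
#' @param tau time to peak (s).
#' @param t_act activation onset time (s).
#' @return An object of class `calcium_transient`.
#' @export
calcium_transient <- function(ca_base = 0.01, ca_peak = 4.35, tau = 0.06,
                              t_act = 0) {
  stopifnot(ca_peak > ca_base, ca_base >= 0, tau > 0)
  structure(list(ca_base = ca_base, ca_peak = ca_peak, tau = tau,
                 t_act = t_act), class = "calcium_transient")
}

#' @describeIn calcium_transient evaluate the waveform at times `t` (s).
#' @param s a `calcium_transient`.
#' @param t time or vector of times (s), non-negative.
#' @export
calcium_at <- function(t, s = calcium_transient()) {
  stopifnot(inherits(s, "calcium_transient"), all(t >= 0))
  tt <- pmax(t - s$t_act, 0)
  s$ca_base + (s$ca_peak - s$ca_base) * (tt / s$tau) * exp(1 - tt / s$tau)
}

#' Initial (resting) active state
#'
#' @param n number of material points.
#' @return An `n x 5` matrix of states `(CaTRPN, z, Q1, Q2, Q3)` at the
#'   fully relaxed fixed point (all zero).
#' @export
active_state_init <- function(n = 1) {
  matrix(0, nrow = n, ncol = 5,
         dimnames = list(NULL, c("CaTRPN", "z", "Q1", "Q2", "Q3")))
}

#' Advance the active contraction state
#'
#' Integrates the excitation-contraction ODE system over `dt` with an
#' explicit scheme: exact exponential updates for the (conditionally
#' stiff) calcium-troponin binding and fading-memory equations, forward
#' Euler for the tropomyosin gate. `nsub` equal substeps guard
#' stiffness when `dt` exceeds the systolic step.
#'
#' @param states state matrix from [active_state_init()] (or a previous
#'   call), one row per material point.
#' @param lambda fibre stretch per point (clamped to the model's
#'   validity range for the length-dependence functions).
#' @param dlambda fibre stretch rate per point (1/s).
#' @param ca intracellular calcium concentration (uM), spatially
#'   uniform.
#' @param dt time step (s), positive.
#' @param params an [active_params()] object.
#' @param T_scale contractility scale multiplying the output tension.
#' @param M extent of infarction per point; tension is scaled by
#'   `(1 - M)`.
#' @param nsub number of substeps (default chosen so the substep is at
#'   most 3e-5 s, the systolic time step).
#' @return A list with the updated `states` and `T`, the active tension
#'   per point in kPa (already scaled by `T_scale` and `1 - M`).
#' @export
step_active_state <- function(states, lambda, dlambda, ca, dt,
                              params = active_params(), T_scale = 1, M = 0,
                              nsub = NULL) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  n <- nrow(states)
  stopifnot(dt > 0, ca >= 0, T_scale >= 0)
  check_extent(M)
  lambda <- rep_len(lambda, n)
  dlambda <- rep_len(dlambda, n)
  scale <- rep_len(T_scale * (1 - M), n)
  if (is.null(nsub)) nsub <- max(1L, ceiling(dt / 3e-5))
  out <- cpp_nhs_step_bulk(states, lambda, dlambda, ca, dt, as.integer(nsub),
                           params$vec, scale)
  if (any(!is.finite(out$states)) || any(!is.finite(out$T))) {
    stop("active model integration produced non-finite state; ",
         "reduce the time step or increase nsub")
  }
  colnames(out$states) <- c("CaTRPN", "z", "Q1", "Q2", "Q3")
  out
}

#' Steady-state isometric active tension
#'
#' Integrates the contraction model at fixed fibre stretch, zero stretch
#' rate, and sustained saturating calcium until the tension reaches its
#' steady state, then scales by `T_scale`. At the resting sarcomere
#' length (`lambda_f = 1`) this returns `T_scale * T_ref`; at the
#' model's maximum sarcomere length (`lambda_f = lambda_max`) the
#' length-dependence factor \eqn{1 + \beta_0(\lambda_f - 1)} applies.
#'
#' @param lambda_f fibre stretch; must lie within the model's validity
#'   range `[lambda_min, lambda_max]`.
#' @param T_scale contractility scale.
#' @param params an [active_params()] object.
#' @param ca calcium concentration held during the computation (uM);
#'   the default is effectively saturating for the troponin buffer.
#' @param dt integration step (s).
#' @param t_max maximum integration time (s).
#' @param tol relative steady-state tolerance on the tension.
#' @return Steady isometric tension in kPa.
#' @examples
#' \donttest{
#' isometric_steady_tension(1, T_scale = 3)     # healthy, resting length
#' }
#' @export
isometric_steady_tension <- function(lambda_f, T_scale = 1,
                                     params = active_params(), ca = 1e4,
                                     dt = 1e-3, t_max = 20, tol = 1e-10) {
  if (length(lambda_f) != 1 || !is.finite(lambda_f) ||
      lambda_f < params$lambda_min - 1e-12 ||
      lambda_f > params$lambda_max + 1e-12) {
    stop(sprintf("fibre stretch %.4g outside the model's validity range [%g, %g]",
                 lambda_f, params$lambda_min, params$lambda_max))
  }
  st <- active_state_init(1)
  t_prev <- -Inf
  t_now <- 0
  steps_per_block <- 200L
  elapsed <- 0
  while (elapsed < t_max) {
    out <- step_active_state(st, lambda_f, 0, ca, dt * steps_per_block,
                             params = params, T_scale = 1,
                             nsub = steps_per_block)
    st <- out$states
    t_now <- out$T[1]
    elapsed <- elapsed + dt * steps_per_block
    if (is.finite(t_prev) && abs(t_now - t_prev) <= tol * max(t_now, 1e-12)) break
    t_prev <- t_now
  }
  T_scale * t_now
}

#' Isometric twitch under the prescribed calcium transient
#'
#' Convenience driver: integrates the contraction model at fixed
#' stretch through one calcium transient and returns the tension-time
#' course (exportable as CSV).
#'
#' @param lambda_f fibre stretch (held fixed).
#' @param transient a [calcium_transient()].
#' @param T_scale contractility scale.
#' @param params an [active_params()] object.
#' @param dt output sampling step (s).
#' @param t_end end time (s).
#' @return A data.frame with columns `t`, `Ca`, `T` (kPa).
#' @export
isometric_twitch <- function(lambda_f = 1, transient = calcium_transient(),
                             T_scale = 1, params = active_params(),
                             dt = 1e-3, t_end = 1) {
  times <- seq(0, t_end, by = dt)
  st <- active_state_init(1)
  Tv <- numeric(length(times))
  cav <- calcium_at(times, transient)
  for (i in seq_along(times)[-1]) {
    out <- step_active_state(st, lambda_f, 0, cav[i - 1], dt,
                             params = params, T_scale = T_scale)
    st <- out$states
    Tv[i] <- out$T[1]
  }
  data.frame(t = times, Ca = cav, T = Tv)
}

#' Fully activated gate level
#'
#' Steady state of the tropomyosin gate at full troponin loading, used
#' to normalize the tension output (internal, exported for testing and
#' diagnostics).
#'
#' @param lambda fibre stretch.
#' @param params an [active_params()] object.
#' @return `z_max(lambda)` in (0, 1).
#' @keywords internal
#' @export
active_zmax <- function(lambda, params = active_params()) {
  vapply(lambda, function(l) cpp_nhs_zmax(l, params$vec), numeric(1))
}
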