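#' Loading protocol
#'
#' Pressure and calcium schedules plus numerical settings for the
#' diastolic inflation and systolic activation phases. Pressures ramp
#' smoothly (cosine ramp) to avoid exciting inertial oscillations; the
#' computation ends when the cavity-volume steady-state criterion fires
#' (relative change below `steady_eps` over the trailing
#' `steady_window`).
#'
#' Presets: `"desk-healthy"` (end-diastolic/end-systolic pressures
#' 8/150 mmHg) and `"desk-mi"` (16/110 mmHg) use desk-scale time steps;
#' `"healthy"` and `"mi-patient"` keep the same pressures with the
#' cluster-scale steps (1.22e-4 s diastole, 3.0e-5 s systole).
#'
#' @param preset one of `"desk-healthy"`, `"desk-mi"`, `"healthy"`,
#'   `"mi-patient"`.
#' @param ... overrides of individual fields (see Details).
#' @details Fields: `p_ed`, `p_es` (mmHg); `dt_dia`, `dt_sys` (s);
#'   `t_ramp_dia`, `t_ramp_sys` (s); `t_max_dia`, `t_max_sys` (s);
#'   `steady_eps` (relative), `steady_window` (s); `check_every`
#'   (steps between volume checks); `damping` (1/s, quasi-static
#'   relaxation: exponential bulk friction on the velocity field that
#'   speeds convergence to the static end-diastolic/end-systolic
#'   equilibria without changing them; 0 in the cluster presets);
#'   `ca_base`, `ca_peak` (uM), `tau_ca` (s, calcium rise time in
#'   systole).
#' @return An object of class `loading_protocol`.
#' @export
loading_protocol <- function(preset = "desk-healthy", ...) {
  preset <- match.arg(preset, c("desk-healthy", "desk-mi", "healthy",
                                "mi-patient"))
  p <- list(p_ed = 8, p_es = 150,
            dt_dia = 4e-4, dt_sys = 4e-4,
            t_ramp_dia = 0.15, t_ramp_sys = 0.05,
            t_max_dia = 1.2, t_max_sys = 1.2,
            steady_eps = 2.5e-3, steady_window = 0.05,
            check_every = 20L, damping = 35,
            ca_base = 0.01, ca_peak = 4.35, tau_ca = 0.06)
  if (preset %in% c("desk-mi", "mi-patient")) {
    p$p_ed <- 16; p$p_es <- 110
  }
  if (preset %in% c("healthy", "mi-patient")) {
    p$dt_dia <- 1.22e-4; p$dt_sys <- 3.0e-5; p$damping <- 0
    p$steady_eps <- 1e-3
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown protocol field(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  if (p$p_ed < 0 || p$p_es < 0) stop("pressures must be non-negative")
  if (p$dt_sys > p$dt_dia) stop("systolic time step must not exceed the diastolic step")
  p$preset <- preset
  class(p) <- "loading_protocol"
  p
}

# smooth (C^1) 0 -> 1 ramp
ramp01 <- function(t, t_ramp) {
  s <- pmin(pmax(t / t_ramp, 0), 1)
  0.5 * (1 - cos(pi * s))
}

#' Steady-state detector on a volume trace
#'
#' Declares steady state when the relative spread of the cavity volume
#' over the trailing window is below `eps`.
#'
#' @param times,volumes trace vectors.
#' @param window trailing window length (s).
#' @param eps relative tolerance.
#' @return Logical.
#' @export
is_steady <- function(times, volumes, window, eps) {
  if (length(times) < 3) return(FALSE)
  t_end <- times[length(times)]
  sel <- times >= t_end - window
  if (sum(sel) < 3 || (t_end - times[1]) < window) return(FALSE)
  v <- volumes[sel]
  (max(v) - min(v)) / max(mean(v), 1e-12) < eps
}

run_phase <- function(model, state, protocol, phase = c("diastole", "systole"),
                      verbose = FALSE) {
  phase <- match.arg(phase)
  dt <- if (phase == "diastole") protocol$dt_dia else protocol$dt_sys
  t_max <- if (phase == "diastole") protocol$t_max_dia else protocol$t_max_sys
  t_ramp <- if (phase == "diastole") protocol$t_ramp_dia else protocol$t_ramp_sys
  t0 <- state$t
  times <- numeric(0); volumes <- numeric(0)
  step <- 0L
  log <- list()
  repeat {
    tt <- state$t - t0
    if (phase == "diastole") {
      p_endo <- protocol$p_ed * ramp01(tt, t_ramp)
      ca <- protocol$ca_base
    } else {
      p_endo <- protocol$p_ed +
        (protocol$p_es - protocol$p_ed) * ramp01(tt, t_ramp)
      ca <- protocol$ca_base +
        (protocol$ca_peak - protocol$ca_base) * ramp01(tt, protocol$tau_ca)
    }
    state <- lv_step(model, state, dt, p_endo, ca, damping = protocol$damping)
    step <- step + 1L
    if (step %% protocol$check_every == 0L) {
      vol <- cavity_volume(model$mesh, state$x)
      times <- c(times, state$t - t0)
      volumes <- c(volumes, vol)
      if (verbose) {
        message(sprintf("[%s] t = %.4f s  p = %6.1f mmHg  V = %7.2f ml  max|J-1| = %.3f  div = %.2e",
                        phase, state$t - t0, p_endo, vol, state$max_J_dev,
                        state$grid$max_div))
      }
      past_ramp <- (state$t - t0) > t_ramp + protocol$steady_window
      if (past_ramp && is_steady(times, volumes, protocol$steady_window,
                                 protocol$steady_eps)) break
    }
    if ((state$t - t0) >= t_max) {
      err <- simpleError(sprintf(
        "%s did not reach steady state within %.3g s (last volumes: %s ml)",
        phase, t_max,
        paste(sprintf("%.2f", utils::tail(volumes, 5)), collapse = ", ")))
      err$trace <- data.frame(t = times, volume = volumes)
      stop(err)
    }
  }
  state$volume <- volumes[length(volumes)]
  state$trace <- data.frame(t = times, volume = volumes)
  state
}

#' Diastolic inflation protocol
#'
#' Ramps the endocardial pressure to the end-diastolic value and holds
#' it until the cavity volume is steady.
#'
#' @param model an [lv_model()].
#' @param protocol a [loading_protocol()].
#' @param state optional initial state (default: rest).
#' @param verbose print a running log.
#' @return The end-diastolic state; `$volume` is the cavity volume
#'   (ml), `$trace` the volume trace.
#' @export
run_diastole <- function(model, protocol = loading_protocol(), state = NULL,
                         verbose = FALSE) {
  if (is.null(state)) state <- lv_state_init(model)
  run_phase(model, state, protocol, "diastole", verbose)
}

#' Systolic activation protocol
#'
#' From an end-diastolic state, rapidly raises the endocardial pressure
#' to the end-systolic value while the intracellular calcium rises to
#' its peak (and is held there), and integrates until the cavity volume
#' is steady.
#'
#' @param model an [lv_model()].
#' @param state_ed end-diastolic state from [run_diastole()].
#' @param protocol a [loading_protocol()].
#' @param verbose print a running log.
#' @return The end-systolic state (same fields as [run_diastole()]).
#' @export
run_systole <- function(model, state_ed, protocol = loading_protocol(),
                        verbose = FALSE) {
  run_phase(model, state_ed, protocol, "systole", verbose)
}

#' Bisection against a volume target
#'
#' Finds a parameter value for which a (monotone) scalar-to-volume
#' runner meets a target volume within a relative tolerance, by
#' bisection. Deterministic given the runner.
#'
#' @param runner function mapping a scalar parameter to a volume (ml).
#' @param target target volume (ml).
#' @param lower,upper bracket; the runner volumes at the endpoints must
#'   straddle the target.
#' @param tol relative volume tolerance (default 0.05, i.e. 5%).
#' @param max_iter maximum bisection iterations.
#' @return A list with `par`, `volume`, `iterations`, and the evaluated
#'   `trace` (data.frame of parameter/volume pairs).
#' @examples
#' bisect_parameter(function(x) 100 - 10 * x, target = 50,
#'                  lower = 0, upper = 10)$par # ~5
#' @export
bisect_parameter <- function(runner, target, lower, upper, tol = 0.05,
                             max_iter = 20L) {
  stopifnot(lower < upper, target > 0, tol > 0)
  v_lo <- runner(lower)
  v_hi <- runner(upper)
  trace <- data.frame(par = c(lower, upper), volume = c(v_lo, v_hi))
  if ((v_lo - target) * (v_hi - target) > 0) {
    stop(sprintf(paste0("bracket [%g, %g] does not straddle the target volume ",
                        "%.4g ml (endpoint volumes %.4g, %.4g ml); widen the bracket"),
                 lower, upper, target, v_lo, v_hi))
  }
  best <- if (abs(v_lo - target) < abs(v_hi - target)) {
    list(par = lower, volume = v_lo)
  } else {
    list(par = upper, volume = v_hi)
  }
  iter <- 0L
  while (abs(best$volume - target) / target >= tol) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop(sprintf("bisection did not converge in %d iterations (best |dV|/V = %.3g)",
                   max_iter, abs(best$volume - target) / target))
    }
    mid <- (lower + upper) / 2
    v_mid <- runner(mid)
    trace <- rbind(trace, data.frame(par = mid, volume = v_mid))
    if ((v_lo - target) * (v_mid - target) <= 0) {
      upper <- mid; v_hi <- v_mid
    } else {
      lower <- mid; v_lo <- v_mid
    }
    if (abs(v_mid - target) < abs(best$volume - target)) {
      best <- list(par = mid, volume = v_mid)
    }
  }
  list(par = best$par, volume = best$volume, iterations = iter, trace = trace)
}

#' Estimate the contractility scale from an end-systolic volume target
#'
#' Runs [run_systole()] from a fixed end-diastolic state inside
#' [bisect_parameter()]: end-systolic volume decreases monotonically
#' with `T_scale`, which is the property bisection relies on.
#'
#' @param model an [lv_model()] (its `T_scale` is overridden).
#' @param state_ed end-diastolic state.
#' @param protocol a [loading_protocol()].
#' @param target_esv target end-systolic volume (ml).
#' @param lower,upper `T_scale` bracket.
#' @param tol relative volume tolerance (default 5%).
#' @param verbose print each candidate run.
#' @return As [bisect_parameter()], with `par` the estimated `T_scale`.
#' @export
estimate_t_scale <- function(model, state_ed, protocol, target_esv,
                             lower = 0.5, upper = 10, tol = 0.05,
                             verbose = FALSE) {
  runner <- function(ts) {
    m <- model
    m$T_scale <- ts
    st <- run_systole(m, state_ed, protocol)
    if (verbose) message(sprintf("  T_scale = %.4g -> ESV = %.2f ml", ts, st$volume))
    st$volume
  }
  bisect_parameter(runner, target_esv, lower, upper, tol = tol)
}

#' Estimate the infarct passive-scaling factor from an EDV target
#'
#' Scales the anisotropic moduli (`a_f`, `a_s`, `a_fs`) jointly by a
#' factor `C_a` and bisects `C_a` so that the end-diastolic volume
#' under the end-diastolic pressure matches the target within
#' tolerance (the end-diastolic volume decreases monotonically with
#' the scaling).
#'
#' @param model an [lv_model()]; its passive parameters provide the
#'   baseline (healthy) moduli.
#' @param protocol a [loading_protocol()].
#' @param target_edv target end-diastolic volume (ml).
#' @param lower,upper bracket for the scaling factor.
#' @param tol relative volume tolerance (default 5%).
#' @param verbose print each candidate run.
#' @return As [bisect_parameter()], with `par` the estimated scaling.
#' @export
estimate_mi_passive_scale <- function(model, protocol, target_edv,
                                      lower = 1, upper = 20, tol = 0.05,
                                      verbose = FALSE) {
  base <- model$passive
  runner <- function(ca) {
    m <- model
    m$passive <- passive_params(a = base$a, b = base$b,
                                af = base$af * ca, bf = base$bf,
                                as_ = base$as_ * ca, bs = base$bs,
                                afs = base$afs * ca, bfs = base$bfs,
                                beta_s = base$beta_s)
    st <- run_diastole(m, protocol)
    if (verbose) message(sprintf("  C_a = %.4g -> EDV = %.2f ml", ca, st$volume))
    st$volume
  }
  bisect_parameter(runner, target_edv, lower, upper, tol = tol)
}
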