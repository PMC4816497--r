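#' Passive orthotropic material parameters
#'
#' Parameters of the invariant-based orthotropic hyperelastic strain
#' energy used for the passive myocardium,
#' \deqn{W = \frac{a}{2b}\left(e^{b(I_1-3)}-1\right)
#'   + \sum_{i=f,s}\frac{a_i}{2b_i}\left(e^{b_i(I_{4i}^\ast-1)^2}-1\right)
#'   + \frac{a_{fs}}{2b_{fs}}\left(e^{b_{fs}I_{8fs}^2}-1\right),}
#' with the modified invariants \eqn{I_{4i}^\ast = \max(I_{4i}, 1)} so
#' that the collagen-fibre families store energy only in extension. The
#' working first Piola-Kirchhoff stress adds a pressure-like reference
#' term and a volumetric penalty,
#' \deqn{\tilde P^p = \partial W/\partial F +
#'   \{-a e^{b(I_1-3)} + \beta_s \log I_3\} F^{-T},}
#' which vanishes identically at \eqn{F = I}.
#'
#' Stress-like inputs are in kPa and stored internally in dyne/cm^2
#' (CGS). The default values are the healthy-subject estimates; the
#' `"mi-patient"` preset scales the anisotropic stiffnesses
#' \eqn{a_f, a_s, a_{fs}} by the passive infarct-remodelling factor
#' `c_a_mi` (default 7.5).
#'
#' @param a,af,as_,afs stress-like moduli (kPa); all must be positive.
#' @param b,bf,bs,bfs dimensionless exponents; all must be positive.
#' @param beta_s volumetric penalty (kPa). The default 100 kPa
#'   (1e6 dyne/cm^2) is a numerical device reinforcing Lagrangian
#'   incompressibility, not a material property.
#' @param preset optional name: `"healthy"` or `"mi-patient"`. A preset
#'   overrides the individual arguments.
#' @param c_a_mi multiplier applied to `af`, `as_`, `afs` for the
#'   `"mi-patient"` preset.
#' @return An object of class `passive_params`: a list of the parameters
#'   in kPa plus `$cgs`, the parameter vector in dyne/cm^2 used by the
#'   kernels, ordered `(a, b, a_f, b_f, a_s, b_s, a_fs, b_fs, beta_s)`.
#' @examples
#' p <- passive_params()
#' p_mi <- passive_params(preset = "mi-patient")
#' p_mi$af / p$af # 7.5
#' @export
passive_params <- function(a = 0.24, b = 5.08, af = 1.46, bf = 4.15,
                           as_ = 0.87, bs = 1.6, afs = 0.3, bfs = 1.3,
                           beta_s = 100, preset = NULL, c_a_mi = 7.5) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("healthy", "mi-patient"))
    if (preset == "mi-patient") {
      af <- af * c_a_mi
      as_ <- as_ * c_a_mi
      afs <- afs * c_a_mi
    }
  }
  vals <- c(a = a, b = b, af = af, bf = bf, as_ = as_, bs = bs,
            afs = afs, bfs = bfs, beta_s = beta_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all passive material parameters must be positive and finite")
  }
  out <- as.list(vals)
  out$cgs <- c(kpa_to_barye(a), b, kpa_to_barye(af), bf, kpa_to_barye(as_),
               bs, kpa_to_barye(afs), bfs, kpa_to_barye(beta_s))
  class(out) <- "passive_params"
  out
}

#' @export
print.passive_params <- function(x, ...) {
  cat("Passive orthotropic parameters (kPa / dimensionless):\n")
  cat(sprintf("  a = %.3g, b = %.3g; a_f = %.3g, b_f = %.3g; a_s = %.3g, b_s = %.3g; a_fs = %.3g, b_fs = %.3g\n",
              x$a, x$b, x$af, x$bf, x$as_, x$bs, x$afs, x$bfs))
  cat(sprintf("  volumetric penalty beta_s = %.3g kPa\n", x$beta_s))
  invisible(x)
}

#' Orthonormal fibre-sheet frame
#'
#' Builds a right-handed orthonormal material frame from approximate
#' fibre and sheet directions: `f0` is normalized, the component of `s0`
#' along `f0` is removed (Gram-Schmidt), and the sheet normal is
#' `n0 = f0 x s0`.
#'
#' @param f0 reference fibre direction (length-3).
#' @param s0 reference sheet direction (length-3), need not be exactly
#'   orthogonal to `f0`.
#' @return A list with unit vectors `f0`, `s0`, `n0`.
#' @examples
#' fr <- fiber_frame(c(1, 0.01, 0), c(0, 1, 0))
#' abs(sum(fr$f0 * fr$s0)) < 1e-15
#' @export
fiber_frame <- function(f0, s0) {
  f0 <- as.numeric(f0); s0 <- as.numeric(s0)
  stopifnot(length(f0) == 3, length(s0) == 3)
  nf <- sqrt(sum(f0^2))
  if (nf < 1e-12) stop("fibre direction must be non-zero")
  f0 <- f0 / nf
  s0 <- s0 - sum(s0 * f0) * f0
  ns <- sqrt(sum(s0^2))
  if (ns < 1e-12) stop("sheet direction must not be parallel to the fibre direction")
  s0 <- s0 / ns
  n0 <- c(f0[2] * s0[3] - f0[3] * s0[2],
          f0[3] * s0[1] - f0[1] * s0[3],
          f0[1] * s0[2] - f0[2] * s0[1])
  list(f0 = f0, s0 = s0, n0 = n0)
}

#' Kinematic invariants of a deformation state
#'
#' Computes \eqn{J}, \eqn{I_1 = \mathrm{tr}(C)}, \eqn{I_3 = J^2}, the
#' fibre/sheet invariants \eqn{I_{4f} = f_0^T C f_0 = f\cdot f},
#' \eqn{I_{4s}}, the shear invariant \eqn{I_{8fs} = f_0^T C s_0}, the
#' clamped invariants \eqn{I_{4i}^\ast = \max(I_{4i},1)}, the deformed
#' axes \eqn{f = F f_0}, \eqn{s = F s_0} and the stretches
#' \eqn{\lambda_f = \sqrt{I_{4f}}}, \eqn{\lambda_s}.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @param frame a `fiber_frame()` (or any list with unit `f0`, `s0`).
#' @return A list of class `deformation_state`.
#' @examples
#' st <- compute_invariants(diag(3), fiber_frame(c(1,0,0), c(0,1,0)))
#' st$I1 # 3
#' @export
compute_invariants <- function(F, frame) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)))
  out <- cpp_ho_invariants(F, frame$f0, frame$s0)
  out$F <- F
  out$frame <- frame
  class(out) <- "deformation_state"
  out
}

#' Passive strain energy density
#'
#' Evaluates the orthotropic strain energy (see [passive_params()]) at a
#' deformation state, optionally modulated by the extent-of-infarction
#' stiffening factor \eqn{(1 + 49M)}. The energy is zero in the
#' reference configuration and the anisotropic terms contribute nothing
#' when the corresponding fibre family is not extended
#' (\eqn{I_{4i} \le 1}).
#'
#' @param state a `deformation_state` from [compute_invariants()].
#' @param params a [passive_params()] object.
#' @param M extent of infarction in `[0, 1]` (default 0, healthy).
#' @return Energy density in kPa (equivalently J/ml x 1e-2).
#' @export
strain_energy <- function(state, params, M = 0) {
  stopifnot(inherits(state, "deformation_state"))
  check_extent(M)
  barye_to_kpa(cpp_ho_energy(state$F, state$frame$f0, state$frame$s0,
                             params$cgs, M))
}

#' Passive first Piola-Kirchhoff stress
#'
#' The working passive stress
#' \eqn{\tilde P^p = \partial W/\partial F + \{-a e^{b(I_1-3)} +
#' \beta_s \log I_3\} F^{-T}}. The infarct factor \eqn{(1+49M)} scales
#' the material response (both \eqn{\partial W/\partial F} and the
#' pressure-like reference term) but not the \eqn{\beta_s} penalty,
#' which is a discretization device.
#'
#' @inheritParams strain_energy
#' @return 3x3 stress tensor in kPa.
#' @export
passive_pk1 <- function(state, params, M = 0) {
  stopifnot(inherits(state, "deformation_state"))
  check_extent(M)
  barye_to_kpa(cpp_ho_pk1(state$F, state$frame$f0, state$frame$s0,
                          params$cgs, M))
}

#' Active fibre stress
#'
#' First Piola-Kirchhoff active stress \eqn{P^a = J T F (f_0 \otimes
#' f_0)} for active tension `T`; the corresponding Cauchy stress is
#' \eqn{\sigma^a = T f \otimes f} with \eqn{f = F f_0}.
#'
#' @param state a `deformation_state`.
#' @param frame optional frame override (defaults to the state's frame).
#' @param T active tension (kPa), must be non-negative.
#' @return 3x3 stress tensor in kPa.
#' @export
active_pk1 <- function(state, frame = state$frame, T = 0) {
  stopifnot(inherits(state, "deformation_state"), T >= 0)
  cpp_active_pk1(state$F, frame$f0, T)
}

#' Cauchy stress from a first Piola-Kirchhoff stress
#'
#' \eqn{\sigma = J^{-1} P F^T}.
#'
#' @param P 3x3 first Piola-Kirchhoff stress.
#' @param F 3x3 deformation gradient with positive determinant.
#' @return 3x3 Cauchy stress (same units as `P`).
#' @export
cauchy_from_pk1 <- function(P, F) {
  P <- as.matrix(P); F <- as.matrix(F)
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("invalid deformation: det(F) <= 0")
  (P %*% t(F)) / J
}

#' Infarct heterogeneity modulation
#'
#' The extent-of-infarction field \eqn{M \in [0,1]} scales the passive
#' strain energy by \eqn{1 + 49M} (the infarct core is 50x stiffer than
#' remote myocardium) and the active tension by \eqn{1 - M} (the core is
#' non-contractile). Both modulations are linear, hence continuous
#' across the border zone.
#'
#' @param x scalar or vector quantity to modulate (an energy or a
#'   tension).
#' @param M extent of infarction, in `[0, 1]`.
#' @param what `"energy"` applies the stiffening factor \eqn{1+49M};
#'   `"tension"` applies the contractility factor \eqn{1-M}.
#' @return The modulated quantity.
#' @examples
#' apply_infarct(1, 1, "energy")   # 50
#' apply_infarct(10, 1, "tension") # 0
#' @export
apply_infarct <- function(x, M, what = c("energy", "tension")) {
  what <- match.arg(what)
  check_extent(M)
  if (what == "energy") x * (1 + 49 * M) else x * (1 - M)
}

check_extent <- function(M) {
  if (any(!is.finite(M)) || any(M < 0) || any(M > 1)) {
    stop("extent of infarction M must lie in [0, 1]")
  }
  invisible(M)
}
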