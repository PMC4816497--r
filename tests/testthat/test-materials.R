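test_that("invariants match direct matrix algebra on random deformations", {
  set.seed(101)
  for (i in 1:20) {
    F <- random_defgrad()
    fr <- random_frame()
    st <- compute_invariants(F, fr)
    C <- t(F) %*% F
    expect_equal(st$I1, sum(diag(C)), tolerance = 1e-12)
    expect_equal(st$I3, det(C), tolerance = 1e-10)
    expect_equal(st$I4f, as.numeric(t(fr$f0) %*% C %*% fr$f0), tolerance = 1e-12)
    expect_equal(st$I4s, as.numeric(t(fr$s0) %*% C %*% fr$s0), tolerance = 1e-12)
    expect_equal(st$I8fs, as.numeric(t(fr$f0) %*% C %*% fr$s0), tolerance = 1e-12)
    expect_equal(st$J, det(F), tolerance = 1e-12)
    expect_equal(st$I4f, st$lambda_f^2, tolerance = 1e-12)
    expect_equal(as.numeric(st$f), as.numeric(F %*% fr$f0), tolerance = 1e-12)
  }
})

test_that("identity deformation gives the reference invariants and zero stress", {
  fr <- fiber_frame(c(1, 0, 0), c(0, 1, 0))
  st <- compute_invariants(diag(3), fr)
  expect_equal(st$I1, 3)
  expect_equal(st$I3, 1)
  expect_equal(st$I4f, 1)
  expect_equal(st$I4s, 1)
  expect_equal(st$I8fs, 0)
  p <- passive_params()
  expect_equal(strain_energy(st, p), 0)
  expect_equal(passive_pk1(st, p), matrix(0, 3, 3))
  expect_equal(cauchy_from_pk1(passive_pk1(st, p), diag(3)), matrix(0, 3, 3))
})

test_that("uniaxial fibre stretch forces I4f = lambda^2 and J = 1", {
  lam <- 1.2
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  st <- compute_invariants(F, fiber_frame(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(st$I4f, lam^2, tolerance = 1e-14)
  expect_equal(st$J, 1, tolerance = 1e-14)
})

test_that("non-positive det(F) is rejected", {
  fr <- fiber_frame(c(1, 0, 0), c(0, 1, 0))
  Fbad <- diag(c(-1, 1, 1))
  expect_error(compute_invariants(Fbad, fr), "det")
})

test_that("strain energy matches an independent term-by-term evaluation", {
  set.seed(102)
  p <- passive_params() # healthy values: a = 0.24 kPa, b = 5.08, ...
  for (i in 1:10) {
    F <- random_defgrad()
    fr <- random_frame()
    st <- compute_invariants(F, fr)
    W_ref <- p$a / (2 * p$b) * (exp(p$b * (st$I1 - 3)) - 1) +
      p$af / (2 * p$bf) * (exp(p$bf * (max(st$I4f, 1) - 1)^2) - 1) +
      p$as_ / (2 * p$bs) * (exp(p$bs * (max(st$I4s, 1) - 1)^2) - 1) +
      p$afs / (2 * p$bfs) * (exp(p$bfs * st$I8fs^2) - 1)
    expect_equal(strain_energy(st, p), W_ref, tolerance = 1e-10)
    expect_gte(strain_energy(st, p), 0)
  }
})

test_that("fibre terms vanish under fibre compression (tension-only clamp)", {
  p <- passive_params()
  lam <- 0.9
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  fr <- fiber_frame(c(1, 0, 0), c(0, 1, 0))
  st <- compute_invariants(F, fr)
  expect_lt(st$I4f, 1)
  W_iso <- p$a / (2 * p$b) * (exp(p$b * (st$I1 - 3)) - 1)
  # sheet direction is stretched here (1/sqrt(lam) > 1), so compare with
  # a configuration where both anisotropic families are compressed
  F2 <- diag(c(0.95, 0.95, 1 / 0.95^2))
  st2 <- compute_invariants(F2, fr)
  expect_lt(st2$I4f, 1)
  expect_lt(st2$I4s, 1)
  W_iso2 <- p$a / (2 * p$b) * (exp(p$b * (st2$I1 - 3)) - 1)
  expect_equal(strain_energy(st2, p), W_iso2, tolerance = 1e-12)
  # and the clamp also kills the fibre contribution to the stress
  P <- passive_pk1(st2, p)
  p_iso <- passive_params(af = 100, bf = p$bf, as_ = 100, bs = p$bs,
                          afs = p$afs, a = p$a, b = p$b, bfs = p$bfs)
  expect_equal(passive_pk1(st2, p_iso), P, tolerance = 1e-12)
  expect_gt(strain_energy(st, p), 0) # isotropic part still stores energy
  expect_equal(strain_energy(st, passive_params(af = 1e3)), strain_energy(st, p),
               tolerance = 1e-12)
  expect_equal(W_iso + p$as_ / (2 * p$bs) * (exp(p$bs * (st$I4s - 1)^2) - 1),
               strain_energy(st, p), tolerance = 1e-12)
})

test_that("passive stress matches finite differences of the energy (dW/dF part)", {
  set.seed(103)
  p <- passive_params()
  n_ok <- 0
  for (i in 1:100) {
    F <- random_defgrad(det_range = c(0.8, 1.2))
    fr <- random_frame()
    # analytic dW/dF
    dW <- cardioib:::cpp_ho_dWdF(F, fr$f0, fr$s0, p$cgs, 0)
    # central finite differences of W
    h <- 1e-6
    fd <- matrix(0, 3, 3)
    for (k in 1:9) {
      Fp <- F; Fp[k] <- Fp[k] + h
      Fm <- F; Fm[k] <- Fm[k] - h
      fd[k] <- (cardioib:::cpp_ho_energy(Fp, fr$f0, fr$s0, p$cgs, 0) -
                  cardioib:::cpp_ho_energy(Fm, fr$f0, fr$s0, p$cgs, 0)) / (2 * h)
    }
    rel <- max(abs(dW - fd)) / max(abs(fd))
    expect_lt(rel, 1e-5)
    n_ok <- n_ok + 1
    # penalty part matches the closed form beta_s log(J^2) F^{-T}
    Pfull <- cardioib:::cpp_ho_pk1(F, fr$f0, fr$s0, p$cgs, 0)
    I1 <- sum(F * F)
    Pref <- dW + (-p$cgs[1] * exp(p$b * (I1 - 3)) +
                    p$cgs[9] * log(det(F)^2)) * t(solve(F))
    expect_equal(Pfull, Pref, tolerance = 1e-9)
  }
  expect_equal(n_ok, 100)
})

test_that("volumetric penalty vanishes exactly at J = 1", {
  set.seed(104)
  fr <- random_frame()
  for (i in 1:5) {
    F <- random_defgrad()
    F <- F / det(F)^(1 / 3) # J = 1 up to roundoff
    p_small <- passive_params(beta_s = 1e-6)
    p_large <- passive_params(beta_s = 1e6)
    st <- compute_invariants(F, fr)
    # a 12-orders-of-magnitude change in beta_s moves nothing beyond the
    # roundoff in log(J^2)
    expect_equal(passive_pk1(st, p_small), passive_pk1(st, p_large),
                 tolerance = 1e-6)
  }
})

test_that("energy is frame-indifferent", {
  set.seed(105)
  p <- passive_params()
  for (i in 1:25) {
    F <- random_defgrad()
    fr <- random_frame()
    Q <- random_rotation()
    W1 <- strain_energy(compute_invariants(F, fr), p)
    W2 <- strain_energy(compute_invariants(Q %*% F, fr), p)
    expect_equal(W2, W1, tolerance = 1e-10)
  }
})

test_that("active stress is consistent with its Cauchy form T f (x) f", {
  set.seed(106)
  for (i in 1:10) {
    F <- random_defgrad()
    fr <- random_frame()
    st <- compute_invariants(F, fr)
    T <- 10
    Pa <- active_pk1(st, T = T)
    sig <- cauchy_from_pk1(Pa, F)
    f <- F %*% fr$f0
    expect_equal(sig, T * f %*% t(f), tolerance = 1e-10)
    # symmetric, rank one, single eigenvalue T lambda_f^2
    expect_equal(sig, t(sig), tolerance = 1e-10)
    ev <- eigen(sig, symmetric = TRUE)$values
    expect_equal(sort(abs(ev), decreasing = TRUE)[1], T * st$lambda_f^2,
                 tolerance = 1e-8)
    expect_lt(abs(ev[2]) + abs(ev[3]), 1e-8 * abs(ev[1]) + 1e-12)
  }
  expect_equal(active_pk1(compute_invariants(diag(3), random_frame()), T = 0),
               matrix(0, 3, 3))
  # at F = identity, Pa = T0 f0 (x) f0
  fr <- fiber_frame(c(0, 1, 0), c(1, 0, 0))
  st0 <- compute_invariants(diag(3), fr)
  expect_equal(active_pk1(st0, T = 5), 5 * fr$f0 %*% t(fr$f0))
})

test_that("cauchy_from_pk1 matches direct evaluation and rejects singular F", {
  set.seed(107)
  for (i in 1:5) {
    F <- random_defgrad()
    P <- matrix(rnorm(9), 3, 3)
    expect_equal(cauchy_from_pk1(P, F), P %*% t(F) / det(F), tolerance = 1e-12)
  }
  expect_equal(cauchy_from_pk1(matrix(0, 3, 3), random_defgrad()), matrix(0, 3, 3))
  F <- random_defgrad()
  P <- matrix(rnorm(9), 3, 3)
  expect_equal(cauchy_from_pk1(P, diag(3)), P)
  expect_error(cauchy_from_pk1(P, matrix(0, 3, 3)), "det")
})

test_that("infarct modulation scales energy by 1+49M and tension by 1-M", {
  expect_equal(apply_infarct(1, 0, "energy"), 1)
  expect_equal(apply_infarct(2, 0, "tension"), 2)
  expect_equal(apply_infarct(1, 1, "energy"), 50)
  expect_equal(apply_infarct(3, 1, "tension"), 0)
  expect_equal(apply_infarct(1, 0.5, "energy"), 25.5)
  expect_equal(apply_infarct(1, 0.5, "tension"), 0.5)
  expect_error(apply_infarct(1, 1.2, "energy"), "M")
  expect_error(apply_infarct(1, -0.1, "tension"), "M")

  # stresses and energies are continuous in M
  set.seed(108)
  F <- random_defgrad()
  fr <- random_frame()
  st <- compute_invariants(F, fr)
  p <- passive_params()
  Ms <- seq(0, 1, by = 0.05)
  Ws <- vapply(Ms, function(m) strain_energy(st, p, M = m), numeric(1))
  expect_equal(Ws, Ws[1] * (1 + 49 * Ms), tolerance = 1e-12)
  Ps <- lapply(Ms, function(m) passive_pk1(st, p, M = m))
  dP <- vapply(seq_along(Ms)[-1],
               function(i) max(abs(Ps[[i]] - Ps[[i - 1]])), numeric(1))
  expect_lt(max(dP), 0.06 * max(abs(Ps[[length(Ms)]])))
})
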