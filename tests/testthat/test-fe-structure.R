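test_that("deformation gradients are exact for reference and affine maps", {
  mesh <- lv_coarse()
  pre <- fe_precompute(mesh)
  F <- deformation_gradient(mesh, pre = pre)
  expect_equal(F, matrix(rep(as.numeric(diag(3)), each = nrow(F)), nrow(F)),
               tolerance = 1e-12)
  A <- matrix(c(1.1, 0.02, 0, 0.01, 0.95, 0.03, 0, 0.02, 1.05), 3, 3)
  x2 <- mesh$nodes %*% t(A) + matrix(c(0.1, 0.2, -0.1), nrow(mesh$nodes), 3,
                                     byrow = TRUE)
  F2 <- deformation_gradient(mesh, x2, pre)
  expect_equal(F2, matrix(rep(as.numeric(A), each = nrow(F2)), nrow(F2)),
               tolerance = 1e-12)
})

test_that("deformation gradient matches finite differences of the displacement field", {
  set.seed(301)
  mesh <- lv_coarse()
  pre <- fe_precompute(mesh)
  # smooth analytic deformation evaluated at the nodes
  phi <- function(X) cbind(X[, 1] + 0.05 * sin(X[, 3]),
                           X[, 2] + 0.04 * X[, 1]^2 / 10,
                           X[, 3] + 0.03 * cos(X[, 1] / 2))
  x <- phi(mesh$nodes)
  F <- deformation_gradient(mesh, x, pre)
  # at each element centroid, compare with the analytic Jacobian
  cents <- cardioib:::element_centroids(mesh)
  h <- 1e-5
  for (e in sample(nrow(F), 10)) {
    Fa <- matrix(0, 3, 3)
    for (j in 1:3) {
      Xp <- Xm <- cents[e, , drop = FALSE]
      Xp[j] <- Xp[j] + h; Xm[j] <- Xm[j] - h
      Fa[, j] <- (phi(Xp) - phi(Xm)) / (2 * h)
    }
    # linear interpolation error over the element
    expect_equal(matrix(F[e, ], 3, 3), Fa, tolerance = 0.05)
  }
})

test_that("zero stress and zero load give identically zero forces", {
  mesh <- lv_coarse()
  pre <- fe_precompute(mesh)
  P0 <- matrix(0, nrow(mesh$elems), 9)
  G <- internal_force(mesh, P0, pre)
  expect_equal(max(abs(G)), 0)
  expect_equal(max(abs(endocardial_pressure_force(mesh, p_endo = 0))), 0)
  expect_equal(max(abs(basal_constraint_force(mesh, mesh$nodes, 1e6, pre))), 0)
  # at the reference configuration the passive stress itself vanishes
  F <- deformation_gradient(mesh, pre = pre)
  P <- cardioib:::cpp_pk1_bulk(F, mesh$f0, mesh$s0, passive_params()$cgs,
                               rep(0, nrow(F)), rep(0, nrow(F)))
  G2 <- internal_force(mesh, P, pre)
  expect_lt(max(abs(G2)), 1e-6)
})

test_that("single-tet assembly matches the hand formula -V P grad(phi)", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh1 <- list(nodes = X, elems = matrix(1:4, 1))
  pre <- fe_precompute(mesh1)
  expect_equal(pre$V0, 1 / 6, tolerance = 1e-14)
  set.seed(302)
  P <- matrix(rnorm(9), 3, 3)
  G <- internal_force(mesh1, matrix(as.numeric(P), 1), pre)
  gradN <- rbind(c(-1, -1, -1), diag(3))
  G_hand <- t(apply(gradN, 1, function(g) -as.numeric(P %*% g) / 6))
  expect_equal(G, G_hand, tolerance = 1e-12)
  # translation invariance
  mesh1b <- mesh1; mesh1b$nodes <- X + 5
  expect_equal(internal_force(mesh1b, matrix(as.numeric(P), 1),
                              fe_precompute(mesh1)), G, tolerance = 1e-12)
})

test_that("virtual work of the assembled forces equals -int P : grad(V)", {
  set.seed(303)
  mesh <- lv_coarse()
  pre <- fe_precompute(mesh)
  x <- mesh$nodes + 0.05 * matrix(rnorm(length(mesh$nodes)), ncol = 3)
  F <- deformation_gradient(mesh, x, pre)
  P <- cardioib:::cpp_pk1_bulk(F, mesh$f0, mesh$s0, passive_params()$cgs,
                               rep(0, nrow(F)), rep(0.5, nrow(F)) * 1e4)
  G <- internal_force(mesh, P, pre)
  for (trial in 1:5) {
    V <- matrix(rnorm(length(mesh$nodes)), ncol = 3)
    lhs <- sum(G * V)
    # independent evaluation: P : grad(V) element-wise (exact, since both
    # are element-wise constant for linear elements)
    rhs <- 0
    for (e in seq_len(nrow(F))) {
      gradV <- matrix(0, 3, 3)
      for (a in 1:4) {
        g <- pre$gradN[e, (3 * a - 2):(3 * a)]
        gradV <- gradV + V[mesh$elems[e, a], ] %*% t(g)
      }
      rhs <- rhs - pre$V0[e] * sum(matrix(P[e, ], 3, 3) * gradV)
    }
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("assembled force is minus the gradient of the discrete energy", {
  set.seed(304)
  mesh <- lv_coarse()
  pre <- fe_precompute(mesh)
  pp <- passive_params()
  x <- mesh$nodes + 0.02 * matrix(rnorm(length(mesh$nodes)), ncol = 3)
  M <- rep(0, nrow(mesh$elems))
  etot <- function(x) {
    F <- cardioib:::cpp_tet_defgrad(x, mesh$elems - 1L, pre$gradN)
    sum(pre$V0 * cardioib:::cpp_energy_bulk(F, mesh$f0, mesh$s0, pp$cgs, M, TRUE))
  }
  # conservative evaluator: dW/dF plus the penalty-potential gradient
  F <- cardioib:::cpp_tet_defgrad(x, mesh$elems - 1L, pre$gradN)
  P <- matrix(0, nrow(F), 9)
  for (e in seq_len(nrow(F))) {
    Fm <- matrix(F[e, ], 3, 3)
    P[e, ] <- as.numeric(cardioib:::cpp_ho_dWdF(Fm, mesh$f0[e, ], mesh$s0[e, ],
                                                pp$cgs, M[e]) +
                           pp$cgs[9] * log(det(Fm)^2) * t(solve(Fm)))
  }
  G <- internal_force(mesh, P, pre)
  h <- 1e-6
  for (i in sample(nrow(x), 6)) {
    for (c in 1:3) {
      xp <- x; xp[i, c] <- xp[i, c] + h
      xm <- x; xm[i, c] <- xm[i, c] - h
      fd <- -(etot(xp) - etot(xm)) / (2 * h)
      expect_equal(G[i, c], fd, tolerance = 1e-6)
    }
  }
})

test_that("follower pressure load has zero resultant on a closed surface", {
  mesh <- lv_coarse()
  allf <- rbind(mesh$faces$endo, mesh$faces$epi, mesh$faces$base)
  G <- cardioib:::cpp_pressure_force(mesh$nodes, allf - 1L, 1e4,
                                     nrow(mesh$nodes))
  expect_lt(max(abs(colSums(G))), 1e-8 * 1e4 * 50)
})

test_that("pressure on a unit square face gives p x area along the normal", {
  # a 1 cm x 1 cm face in the x-y plane, normal +z, two triangles
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  tris <- rbind(c(1, 2, 3), c(1, 3, 4)) # wound so normals point +z
  p <- kpa_to_barye(1)
  G <- cardioib:::cpp_pressure_force(X, tris - 1L, p, 4)
  expect_equal(colSums(G), c(0, 0, -p), tolerance = 1e-10)
})

test_that("basal penalty leaves radial motion free and resists axial/circumferential", {
  mesh <- lv_coarse()
  pre <- fe_precompute(mesh)
  ids <- cardioib:::basal_node_ids(mesh)
  expect_gt(length(ids), 0)
  kappa <- 1e6
  # purely radial displacement -> zero penalty
  x <- mesh$nodes
  i <- ids[1]
  rhat <- c(x[i, 1], x[i, 2], 0) / sqrt(x[i, 1]^2 + x[i, 2]^2)
  x[i, ] <- x[i, ] + 0.1 * rhat
  G <- basal_constraint_force(mesh, x, kappa, pre)
  expect_lt(max(abs(G)), 1e-8 * kappa)
  # axial displacement d -> force -kappa V d along the axis
  x <- mesh$nodes
  x[i, 3] <- x[i, 3] + 0.2
  G <- basal_constraint_force(mesh, x, kappa, pre)
  expect_equal(G[i, ], c(0, 0, -kappa * pre$lumped[i] * 0.2), tolerance = 1e-10)
  # rigid rotation of the basal ring by a small angle: restoring torque
  # matches the per-node sum kappa V r^2 theta
  th <- 1e-3
  x <- mesh$nodes
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  x[ids, ] <- x[ids, ] %*% t(R) # rotate the ring by +th about the axis
  G <- basal_constraint_force(mesh, x, kappa, pre)
  torque <- sum(x[ids, 1] * G[ids, 2] - x[ids, 2] * G[ids, 1])
  r2 <- mesh$nodes[ids, 1]^2 + mesh$nodes[ids, 2]^2
  expect_equal(torque, -kappa * sum(pre$lumped[ids] * r2) * th,
               tolerance = 1e-4)
})

test_that("quadrature weights partition the reference volume and meet the density rule", {
  mesh <- lv_desk()
  pre <- fe_precompute(mesh)
  dx <- 15 / 32
  qp <- build_quadrature(mesh, dx = dx, pre = pre)
  expect_equal(sum(qp$weights), sum(pre$V0), tolerance = 1e-10)
  # per-element spacing audit: lattice spacing (max edge / (order + 1))
  # never exceeds dx / 2
  emax <- cardioib:::element_max_edge(mesh, mesh$nodes)
  expect_true(all(emax / (qp$order + 1) <= dx / 2 + 1e-12))
  # an element smaller than the target spacing gets the minimal rule
  small <- which(emax <= dx / 2)
  if (length(small)) expect_true(all(qp$order[small] == 0))
  # elements with edges of ~3 dx are refined to many points
  big <- which.max(emax)
  expect_gte(qp$order[big], ceiling(emax[big] / (dx / 2)) - 1)
})
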