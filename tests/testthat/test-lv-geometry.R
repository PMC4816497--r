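test_that("generated mesh reproduces the analytic cavity volume and converges", {
  coarse <- lv_coarse()
  fine <- lv_desk()
  err_c <- abs(cavity_volume(coarse) - coarse$cavity_volume_ref) /
    coarse$cavity_volume_ref
  err_f <- abs(cavity_volume(fine) - fine$cavity_volume_ref) /
    fine$cavity_volume_ref
  expect_lt(err_f, 0.02)
  expect_lt(err_f, err_c) # refinement reduces the discretization error
})

test_that("degenerate geometric parameters are rejected", {
  expect_error(make_idealized_lv(wall_thickness = 0), "thickness")
  expect_error(make_idealized_lv(apex_to_base = 1, truncation_height = 2),
               "exceed")
  expect_error(make_idealized_lv(radius_endo = -1), "positive")
})

test_that("mesh is positively oriented with tagged watertight surfaces", {
  mesh <- lv_desk()
  vol <- cardioib:::tet_signed_volumes(mesh$nodes, mesh$elems)
  expect_true(all(vol > 0))
  q <- mesh_quality(mesh)
  expect_gt(q$min_dihedral_deg, 2) # above the quality floor
  # every boundary face is tagged exactly once
  bf <- cardioib:::boundary_faces(mesh$elems)
  expect_equal(nrow(bf),
               nrow(mesh$faces$endo) + nrow(mesh$faces$epi) + nrow(mesh$faces$base))
  # basal plane is planar and orthogonal to the long axis
  base_nodes <- unique(as.integer(mesh$faces$base))
  expect_lt(max(abs(mesh$nodes[base_nodes, 3] - mesh$base_z)), 1e-9)
})

test_that("fibre and sheet angles follow the linear transmural rule", {
  expect_equal(fiber_angles(0)$fiber, -60)
  expect_equal(fiber_angles(0)$sheet, -45)
  expect_equal(fiber_angles(1)$fiber, 60)
  expect_equal(fiber_angles(1)$sheet, 45)
  expect_equal(fiber_angles(0.5)$fiber, 0)
  expect_equal(fiber_angles(0.5)$sheet, 0)
  expect_error(fiber_angles(1.2), "e must lie")
})

test_that("fibre frames are orthonormal with continuous transmural variation", {
  mesh <- lv_desk()
  expect_lt(max(abs(rowSums(mesh$f0 * mesh$s0))), 1e-12)
  expect_lt(max(abs(sqrt(rowSums(mesh$f0^2)) - 1)), 1e-12)
  expect_lt(max(abs(sqrt(rowSums(mesh$s0^2)) - 1)), 1e-12)
  n0 <- cardioib:::rowcross(mesh$f0, mesh$s0)
  expect_lt(max(abs(n0 - mesh$n0)), 1e-12)

  # recovered helix angle matches the rule away from the apex: the angle
  # between f0 and the local circumferential direction equals
  # -60 + 120 e within interpolation error
  sel <- which(cardioib:::element_centroids(mesh)[, 3] > mesh$apex_z + 2)
  ang <- numeric(length(sel))
  for (i in seq_along(sel)) {
    e <- sel[i]
    ca <- sum(mesh$f0[e, ] * mesh$c_elem[e, ])
    sa <- sum(mesh$f0[e, ] * mesh$l_elem[e, ])
    ang[i] <- atan2(sa, ca) * 180 / pi
  }
  rule <- -60 + 120 * mesh$e_elem[sel]
  expect_lt(max(abs(ang - rule)), 1e-6)
})

test_that("region labels partition the mesh and respect the slice geometry", {
  mesh <- lv_desk()
  lab <- assign_regions(mesh)
  expect_equal(nrow(lab), nrow(mesh$nodes))
  expect_true(all(lab$slice %in% 1:7))
  expect_true(all(lab$segment[lab$slice <= 5] %in%
                    c("infsept", "antsept", "ant", "antlat", "inflat", "inf")))
  expect_true(all(lab$segment[lab$slice >= 6] %in%
                    c("sept", "ant", "lat", "inf")))
  # counts sum to the node count (a partition)
  expect_equal(sum(table(lab$slice)), nrow(mesh$nodes))

  # nearest-plane rule: a point exactly on a slice plane gets that slice
  zs <- cardioib:::slice_planes(mesh, 7)
  i3 <- which.min(abs(mesh$nodes[, 3] - zs[3]))
  expect_equal(lab$slice[i3], which.min(abs(mesh$nodes[i3, 3] - zs)))

  # rotation consistency: rotating the mesh and the sector origin
  # together leaves all labels unchanged
  th <- 37
  R <- matrix(c(cos(th * pi / 180), sin(th * pi / 180), 0,
                -sin(th * pi / 180), cos(th * pi / 180), 0, 0, 0, 1), 3, 3)
  mesh_rot <- mesh
  mesh_rot$nodes <- mesh$nodes %*% t(R) # rotate the anatomy by +th
  lab_rot <- assign_regions(mesh_rot, azimuth0 = th)
  expect_equal(lab_rot$segment, lab$segment)
  expect_equal(lab_rot$slice, lab$slice)
})

test_that("infarct extent field follows the linear border-zone rule", {
  mesh <- lv_desk()
  inf <- make_synthetic_infarct(mesh, target_fraction = 0.3, l_bz = 1.0)
  # points in the core have M = 1, far points M = 0
  expect_true(all(inf$M_elem[inf$elements] == 1))
  d <- cardioib:::cpp_point_surface_dist(mesh$nodes, inf$surface$verts,
                                         inf$surface$tris - 1L)
  outside <- !inf$predicate(mesh$nodes)
  expect_equal(inf$M_node[outside], pmax(0, 1 - d[outside] / 1.0),
               tolerance = 1e-12)
  expect_true(all(inf$M_node[d >= 1 & outside] == 0))
  # analytic spot checks on synthetic points at known distances
  probe <- rbind(inf$center)                      # inside
  expect_equal(infarct_extent(probe, inf, l_bz = 1), 1)
  expect_error(infarct_extent(probe, inf, l_bz = -1), "positive")
})

test_that("synthetic infarct hits the requested volume fraction", {
  mesh <- lv_desk()
  inf60 <- make_synthetic_infarct(mesh, target_fraction = 0.6)
  expect_lt(abs(inf60$fraction - 0.6), 0.05)
  inf_all <- make_synthetic_infarct(mesh, target_fraction = 1)
  expect_equal(inf_all$fraction, 1)
  expect_true(all(inf_all$M_elem == 1))
  expect_error(make_synthetic_infarct(mesh, target_fraction = 0),
               "target_fraction")
})

test_that("M is continuous across mesh edges (no jumps beyond edge length / l_bz)", {
  mesh <- lv_coarse()
  inf <- make_synthetic_infarct(mesh, target_fraction = 0.4, l_bz = 1.0)
  # |M(a) - M(b)| <= |a - b| / l_bz for every mesh edge (M is
  # 1-Lipschitz in distance / l_bz)
  el <- mesh$elems
  edges <- unique(rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
                        el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)]))
  dM <- abs(inf$M_node[edges[, 1]] - inf$M_node[edges[, 2]])
  len <- sqrt(rowSums((mesh$nodes[edges[, 1], ] - mesh$nodes[edges[, 2], ])^2))
  expect_true(all(dM <= len / 1.0 + 1e-9))
})

test_that("mesh round-trips through the Gmsh format", {
  mesh <- lv_coarse()
  f <- tempfile(fileext = ".msh")
  write_msh(mesh, f)
  back <- read_msh(f)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-9)
  expect_equal(nrow(back$elems), nrow(mesh$elems))
  expect_equal(sort(as.integer(back$faces$endo)), sort(as.integer(mesh$faces$endo)))
  expect_equal(cavity_volume(back), cavity_volume(mesh), tolerance = 1e-6)
  unlink(f)
})
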