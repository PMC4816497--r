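#' Idealized truncated-ellipsoid left ventricle mesh
#'
#' Generates a tetrahedral mesh of the LV wall between two truncated
#' prolate spheroids sharing a long axis (the z axis; the basal plane is
#' at `z = truncation_height`, the apex points toward negative z). The
#' wall is discretized on a structured (transmural x meridional x
#' azimuthal) lattice, each cell split into six tetrahedra with the
#' Freudenthal/Kuhn pattern (globally conforming, including across the
#' azimuthal seam); at the apex the lattice collapses onto the axis.
#'
#' Surface triangles are tagged `endocardium`, `epicardium`, and
#' `basal plane`, wound so their normals point out of the solid. Each
#' node carries its transmural coordinate `e` (0 at the endocardium, 1
#' at the epicardium) and a local circumferential / longitudinal /
#' transmural basis; each element carries a rule-based fibre-sheet
#' frame from [fiber_angles()].
#'
#' @param radius_endo equatorial endocardial radius (cm).
#' @param wall_thickness wall thickness (cm); must be positive and less
#'   than `radius_endo` is not required, but dimensions must be
#'   feasible.
#' @param apex_to_base distance from the endocardial apex to the basal
#'   plane (cm).
#' @param truncation_height height of the basal plane above the
#'   ellipsoid center (cm); must be smaller than the long semi-axis.
#' @param edge_length target element edge length (cm).
#' @return An object of class `lv_mesh`; see Details.
#' @details The returned list contains `nodes` (n x 3, cm), `elems`
#'   (m x 4, 1-based, positively oriented), `faces` (list of triangle
#'   matrices `endo`, `epi`, `base`), `e_node`, the per-node basis
#'   (`c_hat`, `l_hat`, `r_hat`), per-element fibre frames (`f0`, `s0`,
#'   `n0`, `e_elem`), element reference volumes `V0`, the analytic
#'   cavity volume `cavity_volume_ref` (ml) and the geometry parameters.
#' @examples
#' \donttest{
#' mesh <- make_idealized_lv(edge_length = 0.8)
#' mesh$cavity_volume_ref
#' }
#' @export
make_idealized_lv <- function(radius_endo = 2.0, wall_thickness = 1.1,
                              apex_to_base = 6.0, truncation_height = 2.0,
                              edge_length = 0.45) {
  if (wall_thickness <= 0) stop("wall thickness must be positive")
  if (radius_endo <= 0 || apex_to_base <= 0 || edge_length <= 0)
    stop("all dimensions must be positive")
  c_en <- apex_to_base - truncation_height
  if (c_en <= 0) stop("apex_to_base must exceed truncation_height")
  a_en <- radius_endo
  a_ep <- a_en + wall_thickness
  c_ep <- c_en + wall_thickness
  h <- truncation_height
  if (h >= c_en) stop("truncation_height must be below the endocardial long semi-axis")

  phi_b_en <- acos(h / c_en)
  phi_b_ep <- acos(h / c_ep)

  # lattice resolution from the target edge length
  r_mid <- (a_en + a_ep) / 2
  n_theta <- max(8L, as.integer(round(2 * pi * r_mid / edge_length)))
  arc <- (pi - (phi_b_en + phi_b_ep) / 2) * (c_en + c_ep + a_en + a_ep) / 4
  n_t <- max(4L, as.integer(round(arc / edge_length)))
  n_xi <- max(2L, as.integer(round(wall_thickness / edge_length)))

  # node ids: regular (ixi, it, itheta) for it < n_t, apex axis nodes at it = n_t
  n_reg <- (n_xi + 1L) * n_t * n_theta
  nid <- function(ixi, it, ith) {
    ifelse(it == n_t,
           n_reg + ixi + 1L,
           ixi * (n_t * n_theta) + it * n_theta + (ith %% n_theta) + 1L)
  }
  n_nodes <- n_reg + (n_xi + 1L)

  nodes <- matrix(0, n_nodes, 3)
  e_node <- numeric(n_nodes)
  theta_node <- numeric(n_nodes)
  r_hat <- matrix(0, n_nodes, 3)

  surf_point <- function(a, c, phi, th)
    c(a * sin(phi) * cos(th), a * sin(phi) * sin(th), c * cos(phi))

  for (ixi in 0:n_xi) {
    xi <- ixi / n_xi
    for (it in 0:n_t) {
      # mild anti-clustering toward the apex keeps the collapsed polar
      # elements from degenerating into azimuthal slivers
      tt <- 1 - (1 - it / n_t)^0.7
      phi_en <- phi_b_en + tt * (pi - phi_b_en)
      phi_ep <- phi_b_ep + tt * (pi - phi_b_ep)
      ths <- if (it == n_t) 0 else 2 * pi * (0:(n_theta - 1)) / n_theta
      for (ii in seq_along(ths)) {
        th <- ths[ii]
        pen <- surf_point(a_en, c_en, phi_en, th)
        pep <- surf_point(a_ep, c_ep, phi_ep, th)
        id <- nid(ixi, it, ii - 1L)
        nodes[id, ] <- (1 - xi) * pen + xi * pep
        e_node[id] <- xi
        theta_node[id] <- th
        dvec <- pep - pen
        r_hat[id, ] <- dvec / sqrt(sum(dvec^2))
      }
    }
  }

  # Freudenthal split: 6 tets per lattice cell via axis permutations
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  elems <- vector("list", n_xi * n_t * n_theta)
  idx <- 0L
  for (ixi in 0:(n_xi - 1L)) for (it in 0:(n_t - 1L)) for (ith in 0:(n_theta - 1L)) {
    corner <- function(d) nid(ixi + d[1], it + d[2], ith + d[3])
    cell <- matrix(0L, 6, 4)
    for (p in 1:6) {
      d <- c(0L, 0L, 0L)
      vs <- integer(4)
      vs[1] <- corner(d)
      d[perms[p, 1]] <- 1L; vs[2] <- corner(d)
      d[perms[p, 2]] <- 1L; vs[3] <- corner(d)
      d[perms[p, 3]] <- 1L; vs[4] <- corner(d)
      cell[p, ] <- vs
    }
    idx <- idx + 1L
    elems[[idx]] <- cell
  }
  elems <- do.call(rbind, elems)
  # drop tets collapsed by the apex degeneracy
  keep <- apply(elems, 1, function(v) length(unique(v)) == 4L)
  elems <- elems[keep, , drop = FALSE]
  # orient positively, drop slivers
  vol6 <- tet_signed_volumes(nodes, elems)
  flip <- vol6 < 0
  if (any(flip)) elems[flip, c(3, 4)] <- elems[flip, c(4, 3)]
  vol <- abs(vol6)
  keep <- vol > 1e-10 * edge_length^3
  elems <- elems[keep, , drop = FALSE]

  # boundary faces by node flags
  on_endo <- e_node <= 0 + 1e-12
  on_epi <- e_node >= 1 - 1e-12
  it_of <- rep(NA_integer_, n_nodes)
  # reconstruct it index: regular nodes by construction order; apex nodes it = n_t
  for (ixi in 0:n_xi) for (it in 0:(n_t - 1L)) for (ith in 0:(n_theta - 1L))
    it_of[nid(ixi, it, ith)] <- it
  it_of[(n_reg + 1L):n_nodes] <- n_t
  on_base <- it_of == 0L

  bf <- boundary_faces(elems)
  tag <- function(flags) bf[rowSums(matrix(flags[bf], ncol = 3)) == 3L, , drop = FALSE]
  faces <- list(endo = tag(on_endo), epi = tag(on_epi), base = tag(on_base))
  n_tagged <- sum(vapply(faces, nrow, 1L))
  if (n_tagged != nrow(bf))
    stop("internal mesh error: untagged boundary faces")
  faces <- lapply(faces, orient_outward, nodes = nodes, elems = elems)

  # local basis: circumferential, longitudinal, transmural
  axis_dist <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  c_hat <- cbind(-sin(theta_node), cos(theta_node), 0)
  # make c_hat orthogonal to r_hat, and complete the triad
  dotcr <- rowSums(c_hat * r_hat)
  c_hat <- c_hat - dotcr * r_hat
  c_hat <- c_hat / pmax(sqrt(rowSums(c_hat^2)), 1e-12)
  l_hat <- rowcross(r_hat, c_hat)

  mesh <- list(nodes = nodes, elems = elems,
               faces = faces,
               e_node = e_node, theta_node = theta_node,
               c_hat = c_hat, l_hat = l_hat, r_hat = r_hat,
               long_axis = c(0, 0, 1), base_z = h, apex_z = -c_ep,
               V0 = abs(tet_signed_volumes(nodes, elems)),
               geom = list(radius_endo = a_en, wall_thickness = wall_thickness,
                           a_en = a_en, a_ep = a_ep, c_en = c_en, c_ep = c_ep,
                           truncation_height = h, edge_length = edge_length,
                           n_theta = n_theta, n_t = n_t, n_xi = n_xi),
               cavity_volume_ref = truncated_ellipsoid_cavity_volume(a_en, c_en, h))
  mesh <- add_fiber_frames(mesh)
  class(mesh) <- "lv_mesh"
  mesh
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("Idealized LV mesh: %d nodes, %d tets, cavity %.1f ml (analytic)\n",
              nrow(x$nodes), nrow(x$elems), x$cavity_volume_ref))
  cat(sprintf("  endo/epi/base faces: %d/%d/%d; wall %.2f cm; base at z = %.2f cm\n",
              nrow(x$faces$endo), nrow(x$faces$epi), nrow(x$faces$base),
              x$geom$wall_thickness, x$base_z))
  invisible(x)
}

#' Analytic cavity volume of a truncated prolate spheroid
#'
#' Volume enclosed by the spheroid `x^2/a^2 + y^2/a^2 + z^2/c^2 = 1`
#' below the plane `z = h`, i.e. the cavity bounded by the endocardial
#' surface and its planar basal cap.
#'
#' @param a equatorial semi-axis (cm).
#' @param c long semi-axis (cm).
#' @param h truncation height above center (cm), `|h| <= c`.
#' @return Volume in ml.
#' @export
truncated_ellipsoid_cavity_volume <- function(a, c, h) {
  stopifnot(abs(h) <= c)
  pi * a^2 * ((h + c) - (h^3 + c^3) / (3 * c^2))
}

tet_signed_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 2], , drop = FALSE]
  c_ <- nodes[elems[, 3], , drop = FALSE]
  d <- nodes[elems[, 4], , drop = FALSE]
  u <- b - a; v <- c_ - a; w <- d - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
     u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
     u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

boundary_faces <- function(elems) {
  f <- rbind(elems[, c(2, 3, 4)], elems[, c(1, 4, 3)],
             elems[, c(1, 2, 4)], elems[, c(1, 3, 2)])
  key <- apply(f, 1, function(v) paste(sort(v), collapse = "-"))
  tab <- table(key)
  singles <- names(tab)[tab == 1L]
  f[key %in% singles, , drop = FALSE]
}

# wind boundary triangles so normals point out of the solid (away from
# the owning tet's opposite vertex)
orient_outward <- function(faces, nodes, elems) {
  if (nrow(faces) == 0) return(faces)
  ekey <- new.env(hash = TRUE, parent = emptyenv())
  for (e in seq_len(nrow(elems))) {
    vs <- elems[e, ]
    combs <- list(vs[c(2, 3, 4)], vs[c(1, 3, 4)], vs[c(1, 2, 4)], vs[c(1, 2, 3)])
    for (i in 1:4) {
      k <- paste(sort(combs[[i]]), collapse = "-")
      assign(k, c(e, vs[i]), envir = ekey)
    }
  }
  for (i in seq_len(nrow(faces))) {
    tri <- faces[i, ]
    k <- paste(sort(tri), collapse = "-")
    own <- get(k, envir = ekey)
    opp <- nodes[own[2], ]
    a <- nodes[tri[1], ]; b <- nodes[tri[2], ]; c_ <- nodes[tri[3], ]
    n <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
           (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
           (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
    if (sum(n * (opp - a)) > 0) faces[i, ] <- tri[c(1, 3, 2)]
  }
  faces
}

#' Rule-based transmural fibre and sheet angles
#'
#' Linear transmural rotation of the helix (fibre) angle from -60 to
#' +60 degrees and of the sheet angle from -45 to +45 degrees between
#' the endocardium (`e = 0`) and the epicardium (`e = 1`).
#'
#' @param e transmural coordinate in `[0, 1]`.
#' @return A list with numeric vectors `fiber` and `sheet` (degrees).
#' @examples
#' fiber_angles(0)   # -60, -45
#' fiber_angles(0.5) # 0, 0
#' @export
fiber_angles <- function(e) {
  if (any(!is.finite(e)) || any(e < 0) || any(e > 1))
    stop("transmural coordinate e must lie in [0, 1]")
  list(fiber = -60 + 120 * e, sheet = -45 + 90 * e)
}

add_fiber_frames <- function(mesh) {
  m <- nrow(mesh$elems)
  f0 <- s0 <- n0 <- matrix(0, m, 3)
  c_elem <- l_elem <- r_elem <- matrix(0, m, 3)
  e_elem <- numeric(m)
  for (ei in seq_len(m)) {
    vs <- mesh$elems[ei, ]
    e_bar <- mean(mesh$e_node[vs])
    r <- colMeans(mesh$r_hat[vs, , drop = FALSE])
    r <- r / sqrt(sum(r^2))
    ch <- colMeans(mesh$c_hat[vs, , drop = FALSE])
    ch <- ch - sum(ch * r) * r
    nc <- sqrt(sum(ch^2))
    if (nc < 1e-8) { # apex: circumferential direction degenerate
      ch <- c(1, 0, 0) - r[1] * r
      nc <- sqrt(sum(ch^2))
    }
    ch <- ch / nc
    lh <- c(r[2] * ch[3] - r[3] * ch[2],
            r[3] * ch[1] - r[1] * ch[3],
            r[1] * ch[2] - r[2] * ch[1])
    ang <- fiber_angles(min(max(e_bar, 0), 1))
    alpha <- ang$fiber * pi / 180
    beta <- ang$sheet * pi / 180
    f <- cos(alpha) * ch + sin(alpha) * lh
    fxr <- c(f[2] * r[3] - f[3] * r[2],
             f[3] * r[1] - f[1] * r[3],
             f[1] * r[2] - f[2] * r[1])
    s_pre <- cos(beta) * r + sin(beta) * fxr
    fr <- fiber_frame(f, s_pre)
    f0[ei, ] <- fr$f0; s0[ei, ] <- fr$s0; n0[ei, ] <- fr$n0
    c_elem[ei, ] <- ch; l_elem[ei, ] <- lh; r_elem[ei, ] <- r
    e_elem[ei] <- e_bar
  }
  mesh$f0 <- f0; mesh$s0 <- s0; mesh$n0 <- n0; mesh$e_elem <- e_elem
  mesh$c_elem <- c_elem; mesh$l_elem <- l_elem; mesh$r_elem <- r_elem
  mesh
}

#' Regional division of the LV
#'
#' Divides the LV into seven short-axis slices (1 = basal, 7 = apical)
#' with six 60-degree segments per slice for slices 1-5 (inferior
#' septal, anterior septal, anterior, anterior lateral, inferior
#' lateral, inferior) and four 90-degree segments for the two apical
#' slices (septal, anterior, lateral, inferior). Each point is
#' orthogonally projected onto the nearest slice plane; the slice
#' planes are equally spaced from the basal plane toward the apex.
#'
#' @param mesh an `lv_mesh`.
#' @param n_slices number of slice planes (default 7).
#' @param azimuth0 azimuth (degrees) of the anterior direction; rotates
#'   the segment boundaries.
#' @param at `"node"` or `"element"` (element centroids).
#' @return A data.frame with columns `slice` (integer) and `segment`
#'   (character), one row per node or element.
#' @export
assign_regions <- function(mesh, n_slices = 7, azimuth0 = 0,
                           at = c("node", "element")) {
  at <- match.arg(at)
  pts <- if (at == "node") mesh$nodes else element_centroids(mesh)
  zs <- slice_planes(mesh, n_slices)
  slice <- vapply(pts[, 3], function(z) which.min(abs(z - zs)), integer(1))
  th <- (atan2(pts[, 2], pts[, 1]) * 180 / pi - azimuth0) %% 360
  seg6 <- c("ant", "antlat", "inflat", "inf", "infsept", "antsept")
  seg4 <- c("ant", "lat", "inf", "sept")
  segment <- ifelse(slice <= 5,
                    seg6[pmin(floor(th / 60) + 1, 6)],
                    seg4[pmin(floor(th / 90) + 1, 4)])
  data.frame(slice = slice, segment = segment, stringsAsFactors = FALSE)
}

slice_planes <- function(mesh, n_slices = 7) {
  span <- mesh$base_z - mesh$apex_z
  mesh$base_z - (seq_len(n_slices) - 1) * span / n_slices
}

element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
     mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
}

#' Extent-of-infarction field
#'
#' Evaluates the extent of infarction
#' \deqn{M(X) = 1 \ (X \in U^{in}),\quad
#'       M(X) = 1 - d_{un}(X)/\ell_{bz} \ (0 < d_{un} < \ell_{bz}),\quad
#'       M(X) = 0 \ \mathrm{otherwise},}
#' where \eqn{d_{un}(X)} is the exact minimum Euclidean distance from
#' `X` to the (triangulated boundary of the) infarct region.
#'
#' @param X points (k x 3 matrix or length-3 vector), cm.
#' @param infarct an `infarct_field` from [make_synthetic_infarct()],
#'   or any list with `$predicate` (function of a point matrix
#'   returning logicals) and `$surface` (`list(verts, tris)`).
#' @param l_bz border-zone thickness (cm; default 1 cm = 10 mm).
#' @return Numeric vector of `M` values in `[0, 1]`.
#' @export
infarct_extent <- function(X, infarct, l_bz = 1.0) {
  if (l_bz <= 0) stop("border-zone thickness must be positive")
  if (is.null(dim(X))) X <- matrix(X, ncol = 3)
  inside <- infarct$predicate(X)
  M <- numeric(nrow(X))
  M[inside] <- 1
  if (any(!inside)) {
    d <- cpp_point_surface_dist(X[!inside, , drop = FALSE],
                                infarct$surface$verts,
                                infarct$surface$tris - 1L)
    M[!inside] <- pmax(0, 1 - d / l_bz)
  }
  M
}

#' Synthetic infarct region with border zone
#'
#' Defines a connected infarct region \eqn{U^{in}} as the intersection
#' of the LV wall with an ellipsoidal ball centred on the wall
#' (default: septal, toward the apex), sized by bisection so that the
#' infarcted volume fraction matches `target_fraction`. The extent
#' field `M` is 1 inside the region and decays linearly to 0 across the
#' `l_bz` border zone (see [infarct_extent()]).
#'
#' @param mesh an `lv_mesh`.
#' @param center_azimuth azimuth of the infarct centre (degrees;
#'   default 180, septal for the default segment layout).
#' @param center_height fraction of the base-to-apex span at which the
#'   infarct is centred (0 = base, 1 = apex; default 0.75).
#' @param aspect ratio of longitudinal to circumferential semi-axes of
#'   the ellipsoidal region (default 1.6, apically elongated).
#' @param target_fraction requested infarct volume fraction of the wall
#'   (default 0.6).
#' @param l_bz border-zone thickness (cm).
#' @return An object of class `infarct_field`: `elements` (logical per
#'   element, in \eqn{U^{in}}), `M_node`, `M_elem`, `fraction`
#'   (achieved volume fraction), `l_bz`, `surface` (triangulated
#'   boundary of \eqn{U^{in}}) and `predicate`.
#' @export
make_synthetic_infarct <- function(mesh, center_azimuth = 180,
                                   center_height = 0.75, aspect = 1.6,
                                   target_fraction = 0.6, l_bz = 1.0) {
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must be in (0, 1]")
  th0 <- center_azimuth * pi / 180
  zc <- mesh$base_z + center_height * (mesh$apex_z - mesh$base_z)
  rmid <- (mesh$geom$a_en + mesh$geom$a_ep) / 2 *
    sqrt(max(0, 1 - (zc / ((mesh$geom$c_en + mesh$geom$c_ep) / 2))^2))
  ctr <- c(rmid * cos(th0), rmid * sin(th0), zc)

  predicate_rho <- function(rho) {
    r_perp <- rho
    r_long <- rho * aspect
    function(X) {
      if (is.null(dim(X))) X <- matrix(X, ncol = 3)
      dperp2 <- (X[, 1] - ctr[1])^2 + (X[, 2] - ctr[2])^2
      ((dperp2 / r_perp^2) + ((X[, 3] - ctr[3])^2 / r_long^2)) <= 1
    }
  }
  cents <- element_centroids(mesh)
  vtot <- sum(mesh$V0)
  frac_of <- function(rho) sum(mesh$V0[predicate_rho(rho)(cents)]) / vtot

  span <- mesh$base_z - mesh$apex_z
  lo <- 0.02 * span; hi <- 2.5 * span
  if (target_fraction >= 1 || frac_of(hi) < target_fraction) {
    rho <- hi
  } else {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (frac_of(mid) < target_fraction) lo <- mid else hi <- mid
    }
    rho <- hi
  }
  pred <- predicate_rho(rho)
  in_elem <- pred(cents)
  if (!any(in_elem)) stop("empty infarct region: extent parameters too small")
  fraction <- sum(mesh$V0[in_elem]) / vtot

  surf <- subregion_boundary(mesh, in_elem)
  inf <- list(elements = in_elem, l_bz = l_bz, fraction = fraction,
              predicate = pred, surface = surf, center = ctr, rho = rho)
  inf$M_node <- infarct_extent(mesh$nodes, inf, l_bz)
  inf$M_elem <- infarct_extent(cents, inf, l_bz)
  # points inside infarct elements are in U^in even if the ellipsoidal
  # predicate misses them marginally; enforce M = 1 on core elements
  inf$M_elem[in_elem] <- 1
  class(inf) <- "infarct_field"
  inf
}

#' @export
print.infarct_field <- function(x, ...) {
  cat(sprintf("Synthetic infarct: %.1f%% of wall volume, border zone %.1f mm\n",
              100 * x$fraction, 10 * x$l_bz))
  invisible(x)
}

# triangulated boundary of an element subset
subregion_boundary <- function(mesh, in_elem) {
  sub <- mesh$elems[in_elem, , drop = FALSE]
  tris <- boundary_faces(sub)
  list(verts = mesh$nodes, tris = tris)
}

#' Mesh quality summary
#'
#' @param mesh an `lv_mesh`.
#' @return A list with the minimum signed element volume, the minimum
#'   dihedral angle (degrees) and element count.
#' @export
mesh_quality <- function(mesh) {
  vol <- tet_signed_volumes(mesh$nodes, mesh$elems)
  mind <- Inf
  for (e in seq_len(nrow(mesh$elems))) {
    x <- mesh$nodes[mesh$elems[e, ], ]
    mind <- min(mind, tet_min_dihedral(x))
  }
  list(min_volume = min(vol), min_dihedral_deg = mind * 180 / pi,
       n_elements = nrow(mesh$elems))
}

tet_min_dihedral <- function(x) {
  norms <- rbind(tri_normal(x[2, ], x[3, ], x[4, ]),
                 tri_normal(x[1, ], x[4, ], x[3, ]),
                 tri_normal(x[1, ], x[2, ], x[4, ]),
                 tri_normal(x[1, ], x[3, ], x[2, ]))
  pairs <- utils::combn(4, 2)
  mind <- Inf
  for (i in seq_len(ncol(pairs))) {
    n1 <- norms[pairs[1, i], ]; n2 <- norms[pairs[2, i], ]
    cth <- -sum(n1 * n2)
    mind <- min(mind, acos(max(-1, min(1, cth))))
  }
  mind
}

tri_normal <- function(a, b, c) {
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  n / sqrt(sum(n^2))
}
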