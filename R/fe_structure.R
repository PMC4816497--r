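#' Finite element structural operators
#'
#' Total-Lagrangian machinery on linear tetrahedra: per-element
#' deformation gradients, Galerkin assembly of the weak-form Lagrangian
#' force density, follower endocardial pressure loading, the basal
#' in-plane penalty tether, and IB-compatible quadrature.
#'
#' @name fe_structure
NULL

#' Precompute FE reference data for a mesh
#'
#' Reference shape-function gradients, element volumes and lumped nodal
#' volumes. Called once by [lv_model()]; exported for direct use.
#'
#' @param mesh an `lv_mesh` (or any list with `nodes` and 1-based
#'   `elems`).
#' @return A list with `gradN` (m x 12), `V0` (m), `lumped` (n).
#' @export
fe_precompute <- function(mesh) {
  pre <- cpp_tet_precompute(mesh$nodes, mesh$elems - 1L)
  pre$V0 <- as.numeric(pre$V0)
  pre$lumped <- as.numeric(cpp_lumped_volume(mesh$elems - 1L, pre$V0,
                                             nrow(mesh$nodes)))
  pre
}

#' Per-element deformation gradients
#'
#' Computes the (constant) deformation gradient of every linear
#' tetrahedron for current nodal positions `x`, exact for affine
#' deformations.
#'
#' @param mesh an `lv_mesh`.
#' @param x current nodal positions (n x 3, cm); defaults to the
#'   reference positions (giving identity gradients).
#' @param pre optional [fe_precompute()] result.
#' @return An m x 9 matrix; row `e` is the column-major flattening of
#'   the 3x3 `F` of element `e`.
#' @export
deformation_gradient <- function(mesh, x = mesh$nodes, pre = fe_precompute(mesh)) {
  cpp_tet_defgrad(x, mesh$elems - 1L, pre$gradN)
}

#' Internal (stress-divergence) nodal forces
#'
#' Galerkin assembly of the weak form: for every node `a`,
#' \eqn{G_a = -\sum_e V_e\, P_e \nabla_X \phi_a}, with the test
#' functions not assumed to vanish on the boundary. `P` may come from
#' any stress evaluator (passive, active, or their sum), in dyne/cm^2.
#'
#' @param mesh an `lv_mesh`.
#' @param P m x 9 per-element first Piola-Kirchhoff stresses
#'   (column-major flattened; CGS units).
#' @param pre a [fe_precompute()] result.
#' @return n x 3 nodal forces (dyne).
#' @export
internal_force <- function(mesh, P, pre = fe_precompute(mesh)) {
  cpp_fe_internal_force(mesh$elems - 1L, pre$gradN, pre$V0, P, nrow(mesh$nodes))
}

#' Endocardial follower pressure forces
#'
#' Applies the cavity pressure as a follower traction \eqn{-p\,n} on
#' the deformed endocardial triangles (`n` the outward normal of the
#' solid surface, pointing into the cavity), assembled to nodal forces.
#'
#' @param mesh an `lv_mesh`.
#' @param x current nodal positions (n x 3).
#' @param p_endo cavity pressure in mmHg.
#' @return n x 3 nodal forces (dyne).
#' @export
endocardial_pressure_force <- function(mesh, x = mesh$nodes, p_endo = 0) {
  cpp_pressure_force(x, mesh$faces$endo - 1L, mmhg_to_barye(p_endo),
                     nrow(mesh$nodes))
}

#' Basal in-plane penalty forces
#'
#' Penalizes axial and circumferential displacement of the basal-plane
#' nodes (radial motion is free): each basal node feels
#' \eqn{-\kappa V_a [(d\cdot\hat z)\hat z + (d\cdot\hat\theta)\hat\theta]}
#' for displacement `d`, with `V_a` the lumped nodal volume so that
#' `kappa` is a stiffness density (dyne/cm^2 per cm of displacement,
#' per cm^3).
#'
#' @param mesh an `lv_mesh`.
#' @param x current nodal positions.
#' @param kappa penalty stiffness density (dyne/cm^3/cm displacement).
#' @param pre a [fe_precompute()] result (for the lumped volumes).
#' @param basal_nodes optional indices; default: nodes on the basal
#'   plane of the reference mesh.
#' @return n x 3 nodal forces (dyne).
#' @export
basal_constraint_force <- function(mesh, x, kappa, pre = fe_precompute(mesh),
                                   basal_nodes = NULL) {
  if (is.null(basal_nodes)) basal_nodes <- basal_node_ids(mesh)
  G <- matrix(0, nrow(mesh$nodes), 3)
  if (kappa <= 0 || length(basal_nodes) == 0) return(G)
  X <- mesh$nodes[basal_nodes, , drop = FALSE]
  d <- x[basal_nodes, , drop = FALSE] - X
  # circumferential direction from the reference azimuth
  rr <- sqrt(X[, 1]^2 + X[, 2]^2)
  tx <- -X[, 2] / pmax(rr, 1e-12)
  ty <- X[, 1] / pmax(rr, 1e-12)
  d_ax <- d[, 3]
  d_ci <- d[, 1] * tx + d[, 2] * ty
  w <- kappa * pre$lumped[basal_nodes]
  G[basal_nodes, 1] <- -w * d_ci * tx
  G[basal_nodes, 2] <- -w * d_ci * ty
  G[basal_nodes, 3] <- -w * d_ax
  G
}

basal_node_ids <- function(mesh) {
  which(abs(mesh$nodes[, 3] - mesh$base_z) < 1e-9)
}

#' IB-compatible element quadrature
#'
#' Builds a per-element interior lattice quadrature whose points,
#' mapped to the current configuration, are spaced at most `dx/2`
#' apart (at least two points per Cartesian mesh width), with weights
#' summing exactly to the element reference volume.
#'
#' @param mesh an `lv_mesh`.
#' @param x current nodal positions.
#' @param dx Eulerian grid spacing (cm).
#' @param pre a [fe_precompute()] result.
#' @return A list with `points` (q x 3, current configuration),
#'   `weights` (q, reference volume), `element` (q, 1-based element id)
#'   and `order` (m, lattice order per element).
#' @export
build_quadrature <- function(mesh, x = mesh$nodes, dx, pre = fe_precompute(mesh)) {
  stopifnot(dx > 0)
  ord <- quad_orders(mesh, x, dx)
  qp <- cpp_quad_points(x, mesh$elems - 1L, pre$V0, ord)
  qp$order <- ord
  qp
}

quad_orders <- function(mesh, x, dx) {
  emax <- element_max_edge(mesh, x)
  as.integer(pmax(0, ceiling(emax / (dx / 2)) - 1L))
}

element_max_edge <- function(mesh, x) {
  el <- mesh$elems
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  emax <- rep(0, nrow(el))
  for (pr in pairs) {
    d <- x[el[, pr[1]], , drop = FALSE] - x[el[, pr[2]], , drop = FALSE]
    emax <- pmax(emax, sqrt(rowSums(d^2)))
  }
  emax
}

#' Barycentric interpolation of nodal fields to quadrature points
#'
#' @param mesh an `lv_mesh`.
#' @param qp a [build_quadrature()] result.
#' @param nodal n x k matrix of nodal values.
#' @param x current nodal positions used when `qp` was built.
#' @return q x k matrix of interpolated values.
#' @keywords internal
#' @export
interp_to_quad <- function(mesh, qp, nodal, x) {
  # recover barycentric weights by solving the affine system per point;
  # cheaper: rebuild from lattice structure. We use the element's
  # current vertex matrix and linear shape functions.
  el <- mesh$elems
  q <- nrow(qp$points)
  out <- matrix(0, q, ncol(nodal))
  # group points by element for vectorized solves
  split_idx <- split(seq_len(q), qp$element)
  for (es in names(split_idx)) {
    e <- as.integer(es)
    ids <- split_idx[[es]]
    vs <- el[e, ]
    A <- t(x[vs[2:4], , drop = FALSE]) - matrix(x[vs[1], ], 3, 3)
    rel <- t(qp$points[ids, , drop = FALSE]) - matrix(x[vs[1], ], 3, length(ids))
    bary <- solve(A, rel) # 3 x nids: weights of nodes 2..4
    w1 <- 1 - colSums(bary)
    W <- rbind(w1, bary)
    out[ids, ] <- t(W) %*% nodal[vs, , drop = FALSE]
  }
  out
}
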