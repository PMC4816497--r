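#' Cavity volume of the deformed LV
#'
#' Volume enclosed by the deformed endocardial surface closed by its
#' planar basal cap, computed with the divergence theorem
#' (\eqn{V = \frac{1}{6}\left|\sum_{tri} x_1\cdot(x_2\times x_3)\right|}
#' over the closed, consistently oriented triangulation). The basal cap
#' is a fan over the endocardial rim. Orientation-robust: the absolute
#' value is taken after a closure consistency check.
#'
#' @param mesh an `lv_mesh` (provides the endocardial triangles).
#' @param x current nodal positions (defaults to the reference mesh).
#' @return Cavity volume in ml.
#' @export
cavity_volume <- function(mesh, x = mesh$nodes) {
  tris <- mesh$faces$endo
  # endo triangles are wound outward from the solid (into the cavity);
  # flip them so normals point out of the cavity
  tris <- tris[, c(1, 3, 2), drop = FALSE]
  ring <- surface_rim(tris)
  if (length(ring) < 3) stop("endocardial surface has no closed basal rim")
  ctr <- colMeans(x[ring, , drop = FALSE])
  v <- 0
  for (t in seq_len(nrow(tris))) {
    a <- x[tris[t, 1], ]; b <- x[tris[t, 2], ]; c_ <- x[tris[t, 3], ]
    v <- v + det(rbind(a, b, c_))
  }
  nr <- length(ring)
  for (i in seq_len(nr)) {
    a <- x[ring[i], ]; b <- x[ring[i %% nr + 1], ]
    v <- v + det(rbind(ctr, a, b))
  }
  abs(v) / 6
}

# ordered rim (boundary loop) of an open triangulated surface, oriented
# consistently with the triangle winding
surface_rim <- function(tris) {
  edges <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  tab <- table(key)
  open_edges <- edges[key %in% names(tab)[tab == 1L], , drop = FALSE]
  if (nrow(open_edges) == 0) return(integer(0))
  nxt <- open_edges[, 2]
  names(nxt) <- open_edges[, 1]
  start <- open_edges[1, 1]
  ring <- integer(0)
  cur <- start
  for (i in seq_len(nrow(open_edges))) {
    ring <- c(ring, cur)
    cur <- nxt[[as.character(cur)]]
    if (is.null(cur) || cur == start) break
  }
  # the rim follows the flipped winding; reverse so the cap fan closes
  # the surface with outward (positive) orientation
  rev(ring)
}

#' Green-Lagrange strain components in the cardiac frame
#'
#' Per-element Green-Lagrange strain \eqn{E = (F^T F - I)/2} relative
#' to the (early-diastolic) reference configuration, projected onto
#' the reference cylindrical frame about the long axis: circumferential
#' \eqn{\hat c}, radial \eqn{\hat r} (horizontal, outward) and
#' longitudinal \eqn{\hat l} (the long axis), plus the fibre strain
#' \eqn{E_{ff} = \hat f_0^T E \hat f_0}.
#'
#' @param mesh an `lv_mesh`.
#' @param x deformed nodal positions.
#' @param pre optional [fe_precompute()] result.
#' @return A data.frame with one row per element: `E_cc`, `E_rr`,
#'   `E_ll`, `E_cr`, `E_cl`, `E_rl`, `E_ff`.
#' @export
strain_components <- function(mesh, x, pre = fe_precompute(mesh)) {
  F <- cpp_tet_defgrad(x, mesh$elems - 1L, pre$gradN)
  m <- nrow(F)
  cents <- element_centroids(mesh)
  rr <- sqrt(cents[, 1]^2 + cents[, 2]^2)
  r_hat <- cbind(cents[, 1] / pmax(rr, 1e-12), cents[, 2] / pmax(rr, 1e-12), 0)
  c_hat <- cbind(-r_hat[, 2], r_hat[, 1], 0)
  l_hat <- matrix(rep(c(0, 0, 1), each = m), m, 3)
  out <- matrix(0, m, 7)
  for (e in seq_len(m)) {
    Fe <- matrix(F[e, ], 3, 3)
    E <- (crossprod(Fe) - diag(3)) / 2
    ch <- c_hat[e, ]; rh <- r_hat[e, ]; lh <- l_hat[e, ]
    f0 <- mesh$f0[e, ]
    out[e, ] <- c(ch %*% E %*% ch, rh %*% E %*% rh, lh %*% E %*% lh,
                  ch %*% E %*% rh, ch %*% E %*% lh, rh %*% E %*% lh,
                  f0 %*% E %*% f0)
  }
  colnames(out) <- c("E_cc", "E_rr", "E_ll", "E_cr", "E_cl", "E_rl", "E_ff")
  as.data.frame(out)
}

#' Fibre stress
#'
#' Projects the structural Cauchy stress onto the deformed unit fibre
#' direction: \eqn{\sigma_{ff} = \hat f^T \sigma \hat f} with
#' \eqn{\hat f = F f_0 / |F f_0|} and
#' \eqn{\sigma = J^{-1} P F^T (- p I)}. The fluid pressure
#' contribution `p_fluid` is optional (pure-structure analyses omit
#' it).
#'
#' @param mesh an `lv_mesh`.
#' @param x deformed nodal positions.
#' @param P per-element first Piola-Kirchhoff stresses (m x 9, kPa),
#'   e.g. passive + active.
#' @param p_fluid optional per-element fluid pressure (kPa) added as
#'   \eqn{-p I} to the Cauchy stress.
#' @param pre optional [fe_precompute()] result.
#' @return Numeric vector of per-element fibre stresses (kPa).
#' @export
fibre_stress <- function(mesh, x, P, p_fluid = NULL,
                         pre = fe_precompute(mesh)) {
  F <- cpp_tet_defgrad(x, mesh$elems - 1L, pre$gradN)
  m <- nrow(F)
  if (is.null(p_fluid)) p_fluid <- rep(0, m)
  out <- numeric(m)
  for (e in seq_len(m)) {
    Fe <- matrix(F[e, ], 3, 3)
    Pe <- matrix(P[e, ], 3, 3)
    sig <- (Pe %*% t(Fe)) / det(Fe) - p_fluid[e] * diag(3)
    f <- Fe %*% mesh$f0[e, ]
    f <- f / sqrt(sum(f^2))
    out[e] <- as.numeric(t(f) %*% sig %*% f)
  }
  out
}

#' Per-element total structural stress of a model state
#'
#' Convenience evaluator used by the post-processing examples: passive
#' plus active first Piola-Kirchhoff stress at the given positions.
#'
#' @param model an [lv_model()].
#' @param state a coupled state (uses `x` and the element tensions
#'   `T_elem` if present).
#' @return m x 9 matrix of stresses (kPa).
#' @export
structural_pk1 <- function(model, state) {
  mesh <- model$mesh
  F <- cpp_tet_defgrad(state$x, mesh$elems - 1L, model$pre$gradN)
  T_elem <- state$T_elem
  if (is.null(T_elem)) T_elem <- rep(0, nrow(F))
  P <- cpp_pk1_bulk(F, mesh$f0, mesh$s0, model$passive$cgs, model$M_elem,
                    kpa_to_barye(T_elem))
  barye_to_kpa(P)
}

#' Per-slice rotation about the long axis
#'
#' Mean change of the azimuthal angle of the nodes of each short-axis
#' slice between two configurations (end-diastole to end-systole),
#' in degrees; positive is counter-clockwise viewed from the base.
#' Nodes within `r_min` of the axis are excluded (their azimuth is
#' ill-conditioned).
#'
#' @param mesh an `lv_mesh` (slices assigned on the reference nodes).
#' @param x_ref,x_cur nodal positions of the two configurations.
#' @param n_slices number of slices (default 7).
#' @param r_min axis exclusion radius (cm).
#' @return A data.frame with `slice` and `rotation_deg`.
#' @export
slice_rotation <- function(mesh, x_ref, x_cur, n_slices = 7, r_min = 0.5) {
  lab <- assign_regions(mesh, n_slices = n_slices, at = "node")
  th_ref <- atan2(x_ref[, 2], x_ref[, 1])
  th_cur <- atan2(x_cur[, 2], x_cur[, 1])
  dth <- (th_cur - th_ref + pi) %% (2 * pi) - pi
  r <- sqrt(x_ref[, 1]^2 + x_ref[, 2]^2)
  keep <- r >= r_min
  agg <- tapply(dth[keep] * 180 / pi, lab$slice[keep], mean)
  data.frame(slice = as.integer(names(agg)),
             rotation_deg = as.numeric(agg))
}

#' Regional mean and standard deviation tables
#'
#' Aggregates a per-point (or per-element) quantity over the LV
#' regional division: mean, SD and count per (slice, segment), and the
#' same per longitudinal level (basal = slices 1-2, middle = 3-5,
#' apical = 6-7) and segment.
#'
#' @param values numeric vector, one value per row of `labels`.
#' @param labels a data.frame from [assign_regions()] (columns `slice`,
#'   `segment`).
#' @param file optional path: writes the two tables as one CSV.
#' @return A list of data.frames `by_slice` and `by_level`. Cells with
#'   no members are kept as `NA` rows (flagged, not an error).
#' @export
regional_tables <- function(values, labels, file = NULL) {
  stopifnot(length(values) == nrow(labels))
  seg6 <- c("infsept", "antsept", "ant", "antlat", "inflat", "inf")
  seg4 <- c("sept", "ant", "lat", "inf")
  agg <- function(df) {
    out <- do.call(rbind, lapply(split(df$value, df$group), function(v) {
      data.frame(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
                 n = length(v))
    }))
    out$group <- rownames(out)
    rownames(out) <- NULL
    out
  }
  grid_slice <- rbind(expand.grid(slice = 1:5, segment = seg6,
                                  stringsAsFactors = FALSE),
                      expand.grid(slice = 6:7, segment = seg4,
                                  stringsAsFactors = FALSE))
  df <- data.frame(value = values, slice = labels$slice,
                   segment = labels$segment, stringsAsFactors = FALSE)
  df$group <- paste(df$slice, df$segment, sep = ":")
  a <- agg(df)
  grid_slice$group <- paste(grid_slice$slice, grid_slice$segment, sep = ":")
  by_slice <- merge(grid_slice, a, by = "group", all.x = TRUE)
  by_slice <- by_slice[order(by_slice$slice, match(by_slice$segment, c(seg6, seg4))),
                       c("slice", "segment", "mean", "sd", "n")]
  rownames(by_slice) <- NULL

  lvl <- cut(labels$slice, breaks = c(0, 2, 5, 7),
             labels = c("basal", "middle", "apical"))
  df2 <- data.frame(value = values, level = as.character(lvl),
                    segment = labels$segment, stringsAsFactors = FALSE)
  df2$group <- paste(df2$level, df2$segment, sep = ":")
  b <- agg(df2)
  grid_lvl <- rbind(expand.grid(level = c("basal", "middle"), segment = seg6,
                                stringsAsFactors = FALSE),
                    expand.grid(level = "apical", segment = seg4,
                                stringsAsFactors = FALSE))
  grid_lvl$group <- paste(grid_lvl$level, grid_lvl$segment, sep = ":")
  by_level <- merge(grid_lvl, b, by = "group", all.x = TRUE)
  by_level <- by_level[order(match(by_level$level, c("basal", "middle", "apical")),
                             match(by_level$segment, c(seg6, seg4))),
                       c("level", "segment", "mean", "sd", "n")]
  rownames(by_level) <- NULL

  out <- list(by_slice = by_slice, by_level = by_level)
  if (!is.null(file)) {
    con <- file(file, "w")
    writeLines("# per-slice regional statistics", con)
    utils::write.csv(by_slice, con, row.names = FALSE)
    writeLines("# per-level (basal/middle/apical) regional statistics", con)
    utils::write.csv(by_level, con, row.names = FALSE)
    close(con)
  }
  out
}
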