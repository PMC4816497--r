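#' Export a mesh and fields as legacy VTK
#'
#' Writes an ASCII legacy VTK unstructured grid with the tetrahedra,
#' optional point data and cell data arrays (scalars or 3-vectors),
#' viewable in ParaView.
#'
#' @param mesh an `lv_mesh`.
#' @param file output path (`.vtk`).
#' @param x nodal positions to write (defaults to reference).
#' @param point_data named list of per-node vectors/matrices.
#' @param cell_data named list of per-element vectors/matrices.
#' @return `file`, invisibly.
#' @export
write_vtk <- function(mesh, file, x = mesh$nodes, point_data = list(),
                      cell_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(x); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "cardioib LV mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", n), con)
  utils::write.table(format(x, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  write_vtk_data <- function(data, count, kind) {
    writeLines(sprintf("%s %d", kind, count), con)
    for (nm in names(data)) {
      val <- data[[nm]]
      if (is.null(dim(val))) {
        writeLines(sprintf("SCALARS %s double 1", nm), con)
        writeLines("LOOKUP_TABLE default", con)
        writeLines(format(val, digits = 10), con)
      } else {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(format(val, digits = 10), con, row.names = FALSE,
                           col.names = FALSE, quote = FALSE)
      }
    }
  }
  if (length(point_data)) write_vtk_data(point_data, n, "POINT_DATA")
  if (length(cell_data)) write_vtk_data(cell_data, m, "CELL_DATA")
  invisible(file)
}

#' Export a mesh in Gmsh v2.2 ASCII format
#'
#' Writes the tetrahedra (physical/elementary tag 1) and the tagged
#' surface triangles (physical tags: 1 endocardium, 2 epicardium,
#' 3 basal plane).
#'
#' @param mesh an `lv_mesh`.
#' @param file output path (`.msh`).
#' @return `file`, invisibly.
#' @export
write_msh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(n)), con)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(n), mesh$nodes[, 1],
                     mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("$EndNodes", con)
  tris <- rbind(cbind(1L, mesh$faces$endo), cbind(2L, mesh$faces$epi),
                cbind(3L, mesh$faces$base))
  m <- nrow(mesh$elems); k <- nrow(tris)
  writeLines(c("$Elements", as.character(m + k)), con)
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", seq_len(k), tris[, 1],
                     tris[, 1], tris[, 2], tris[, 3], tris[, 4]), con)
  writeLines(sprintf("%d 4 2 1 1 %d %d %d %d", k + seq_len(m),
                     mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3],
                     mesh$elems[, 4]), con)
  writeLines("$EndElements", con)
  invisible(file)
}

#' Import a tetrahedral mesh from Gmsh v2.2 ASCII
#'
#' Reads nodes, tetrahedra and tagged surface triangles (physical tags
#' 1/2/3 = endocardium/epicardium/basal plane) and rebuilds the
#' derived `lv_mesh` structure. The transmural coordinate of an
#' imported mesh is approximated by the distance ratio
#' `d_endo / (d_endo + d_epi)` to the tagged surfaces.
#'
#' @param file path to a `.msh` file written by [write_msh()] or a
#'   compatible exporter.
#' @return An `lv_mesh` (without the analytic geometry fields).
#' @export
read_msh <- function(file) {
  lines <- readLines(file)
  nstart <- which(lines == "$Nodes") + 2L
  nn <- as.integer(lines[nstart - 1L])
  nd <- utils::read.table(text = lines[nstart:(nstart + nn - 1L)])
  nodes <- as.matrix(nd[order(nd[[1]]), 2:4])
  dimnames(nodes) <- NULL
  estart <- which(lines == "$Elements") + 2L
  ne <- as.integer(lines[estart - 1L])
  elines <- lines[estart:(estart + ne - 1L)]
  parts <- strsplit(elines, " ")
  tets <- list(); tris <- list(); tags <- integer(0)
  for (p in parts) {
    v <- as.integer(p)
    ntag <- v[3]
    conn <- v[(4 + ntag):length(v)]
    if (v[2] == 4L) tets[[length(tets) + 1L]] <- conn
    if (v[2] == 2L) {
      tris[[length(tris) + 1L]] <- conn
      tags <- c(tags, v[4])
    }
  }
  elems <- do.call(rbind, tets)
  tri <- do.call(rbind, tris)
  faces <- list(endo = tri[tags == 1L, , drop = FALSE],
                epi = tri[tags == 2L, , drop = FALSE],
                base = tri[tags == 3L, , drop = FALSE])
  vol6 <- tet_signed_volumes(nodes, elems)
  flip <- vol6 < 0
  if (any(flip)) elems[flip, c(3, 4)] <- elems[flip, c(4, 3)]

  d_en <- cpp_point_surface_dist(nodes, nodes, faces$endo - 1L)
  d_ep <- cpp_point_surface_dist(nodes, nodes, faces$epi - 1L)
  e_node <- d_en / pmax(d_en + d_ep, 1e-12)
  theta_node <- atan2(nodes[, 2], nodes[, 1])
  # transmural direction from the gradient of the distance-ratio field
  # approximated radially; adequate for convex walls
  rr <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  r_hat <- cbind(nodes[, 1] / pmax(rr, 1e-12), nodes[, 2] / pmax(rr, 1e-12), 0)
  c_hat <- cbind(-sin(theta_node), cos(theta_node), 0)
  l_hat <- rowcross(r_hat, c_hat)
  base_z <- max(nodes[, 3])
  mesh <- list(nodes = nodes, elems = elems, faces = faces, e_node = e_node,
               theta_node = theta_node, c_hat = c_hat, l_hat = l_hat,
               r_hat = r_hat, long_axis = c(0, 0, 1), base_z = base_z,
               apex_z = min(nodes[, 3]),
               V0 = abs(tet_signed_volumes(nodes, elems)),
               geom = list(a_en = NA, a_ep = NA, c_en = NA, c_ep = NA,
                           wall_thickness = NA, edge_length = NA),
               cavity_volume_ref = NA)
  mesh <- add_fiber_frames(mesh)
  class(mesh) <- "lv_mesh"
  mesh
}

#' Export the Eulerian grid fields as legacy VTK
#'
#' Writes the staggered velocity (averaged to cell centres) and the
#' pressure as a legacy VTK structured-points dataset for inspection in
#' ParaView.
#'
#' @param grid a [staggered_grid()].
#' @param file output path (`.vtk`).
#' @return `file`, invisibly.
#' @export
write_vtk_grid <- function(grid, file) {
  n <- grid$n
  uc <- 0.5 * (grid$u[1:n[1], , , drop = FALSE] +
                 grid$u[2:(n[1] + 1), , , drop = FALSE])
  vc <- 0.5 * (grid$v[, 1:n[2], , drop = FALSE] +
                 grid$v[, 2:(n[2] + 1), , drop = FALSE])
  wc <- 0.5 * (grid$w[, , 1:n[3], drop = FALSE] +
                 grid$w[, , 2:(n[3] + 1), drop = FALSE])
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cardioib fluid grid", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
               sprintf("ORIGIN %.8g %.8g %.8g",
                       grid$origin[1] + grid$dx / 2,
                       grid$origin[2] + grid$dx / 2,
                       grid$origin[3] + grid$dx / 2),
               sprintf("SPACING %.8g %.8g %.8g", grid$dx, grid$dx, grid$dx),
               sprintf("POINT_DATA %d", prod(n)),
               "VECTORS velocity double"), con)
  utils::write.table(cbind(as.numeric(uc), as.numeric(vc), as.numeric(wc)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(grid$p), digits = 8), con)
  invisible(file)
}
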