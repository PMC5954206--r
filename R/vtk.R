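# Legacy-ASCII VTK export of meshes and deformed states for inspection in
# ParaView-style viewers. Written by hand: no VTK writer exists in the
# installed R stack, and the legacy unstructured-grid format is a few
# dozen lines.

#' Export a cross-section mesh or deformed state to legacy VTK
#'
#' Writes an unstructured grid of quadrilaterals with optional point data
#' (displacements) and cell data (layer tag, Cauchy stress invariants,
#' contact pressure where available).
#'
#' @param mesh a [build_cross_section] mesh.
#' @param path output file path (`.vtk`).
#' @param result optional `reapposition_result` or `pressurized_state`
#'   whose displacements and centroid stresses are exported; the deformed
#'   coordinates are written as the geometry.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, result = NULL) {
  stopifnot(inherits(mesh, "cross_section_mesh"))
  nodes <- mesh$nodes
  u <- NULL
  if (!is.null(result)) {
    u <- cbind(result$u[seq(1, 2 * nrow(nodes), 2)],
               result$u[seq(2, 2 * nrow(nodes), 2)])
    nodes <- nodes + u
  }
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "dissected aorta cross-section", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(cbind(nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(9L, m)), con)   # VTK_QUAD
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS layer int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$layer))), con)
  if (!is.null(result) && !is.null(result$sys$sigma_centroid)) {
    s <- result$sys$sigma_centroid
    writeLines(c("SCALARS mean_stress double 1", "LOOKUP_TABLE default"), con)
    writeLines(format((s[, 1] + s[, 2]) / 2, digits = 8), con)
    writeLines(c("SCALARS max_shear double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(sqrt(((s[, 1] - s[, 2]) / 2)^2 + s[, 3]^2), digits = 8), con)
  }
  if (!is.null(u)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    writeLines("VECTORS displacement double", con)
    utils::write.table(cbind(u, 0), con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
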