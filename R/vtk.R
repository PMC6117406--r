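# Minimal legacy-ASCII VTK unstructured-grid writer for hexahedral meshes
# (displacement point data; layer/region/fiber/strain cell data). Viewable in
# ParaView; kept dependency-free.

#' Write a mesh snapshot as a legacy VTK file
#'
#' @param mesh an `lv_mesh`.
#' @param file output path (`.vtk`).
#' @param u optional displacement vector written as point data (and used to
#'   deform the coordinates when `deform = TRUE`).
#' @param cell_data named list of per-element scalar vectors or 3-column
#'   matrices (written as vectors).
#' @param deform write deformed coordinates.
#' @return `file`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, file, u = NULL, cell_data = list(),
                           deform = FALSE) {
  X <- mesh$nodes
  nn <- nrow(X); ne <- nrow(mesh$conn)
  if (!is.null(u) && deform)
    X <- X + matrix(u, ncol = 3, byrow = TRUE)
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("lvmech snapshot")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", nn)
  writeLines(paste(X[, 1], X[, 2], X[, 3]), con)
  wl("CELLS %d %d", ne, 9 * ne)
  writeLines(paste(8, mesh$conn[, 1] - 1, mesh$conn[, 2] - 1,
                   mesh$conn[, 3] - 1, mesh$conn[, 4] - 1,
                   mesh$conn[, 5] - 1, mesh$conn[, 6] - 1,
                   mesh$conn[, 7] - 1, mesh$conn[, 8] - 1), con)
  wl("CELL_TYPES %d", ne)
  writeLines(as.character(rep(12L, ne)), con)

  if (!is.null(u)) {
    um <- matrix(u, ncol = 3, byrow = TRUE)
    wl("POINT_DATA %d", nn)
    wl("VECTORS displacement double")
    writeLines(paste(um[, 1], um[, 2], um[, 3]), con)
  }
  cd <- c(list(layer = mesh$layer), cell_data)
  wl("CELL_DATA %d", ne)
  for (nm in names(cd)) {
    v <- cd[[nm]]
    if (is.matrix(v)) {
      wl("VECTORS %s double", nm)
      writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
    } else {
      wl("SCALARS %s double 1", nm)
      wl("LOOKUP_TABLE default")
      writeLines(as.character(as.numeric(v)), con)
    }
  }
  invisible(file)
}
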