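#' Export a finite-element result to VTK and delimited text
#'
#' Writes a legacy-ASCII VTK unstructured grid (`.vtk`) with the mesh, the
#' nodal displacement vector field and the per-element equivalent (von
#' Mises) stress, plus a delimited force-displacement table (`.csv`) next
#' to it.
#'
#' @param result A [run_compression()] result.
#' @param path Output path without extension (or ending in `.vtk`).
#' @return Invisibly, a character vector with the two file paths.
#' @export
export_fields <- function(result, path) {
  if (!inherits(result, "fem_result")) abort("`result` must be a fem_result.")
  base <- sub("\\.vtk$", "", path)
  vtk <- paste0(base, ".vtk")
  csv <- paste0(base, "_force_displacement.csv")
  dir <- dirname(vtk)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) abort(sprintf("Cannot create directory '%s'.", dir))
  }
  write_vtk(result$mesh, vtk,
            point_vectors = list(displacement = result$U),
            cell_scalars = list(von_mises = result$von_mises))
  write.csv(tidy.fem_result(result), csv, row.names = FALSE)
  invisible(c(vtk = vtk, csv = csv))
}

#' Write a hexahedral mesh (with fields) as legacy-ASCII VTK
#'
#' @param mesh A `cylinder_mesh`.
#' @param path Output file path.
#' @param point_vectors Named list of N x 3 nodal vector fields.
#' @param cell_scalars Named list of per-element scalar fields.
#' @return Invisibly, `path`.
#' @export
write_vtk <- function(mesh, path, point_vectors = list(),
                      cell_scalars = list()) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("Cannot open '%s' for writing.", path))
  })
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  e <- nrow(mesh$elems)
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  writeLines(c("# vtk DataFile Version 3.0",
               "hexahedral cylinder mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1, function(r) paste(fmt(r), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", e, e * 9L), con)
  writeLines(apply(mesh$elems, 1,
                   function(r) paste(c(8L, r - 1L), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", e), con)
  writeLines(rep("12", e), con)
  if (length(point_vectors)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_vectors)) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(apply(point_vectors[[nm]], 1,
                       function(r) paste(fmt(r), collapse = " ")), con)
    }
  }
  if (length(cell_scalars)) {
    writeLines(sprintf("CELL_DATA %d", e), con)
    for (nm in names(cell_scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(fmt(cell_scalars[[nm]]), con)
    }
  }
  invisible(path)
}

#' Read back a legacy-ASCII VTK unstructured grid written by [write_vtk()]
#'
#' Minimal reader used for round-trip verification: recovers point and
#' cell counts, connectivity, and the names and values of the exported
#' fields.
#'
#' @param path VTK file path.
#' @return A list: `points` (N x 3), `cells` (E x 8), `point_vectors`,
#'   `cell_scalars` (named lists).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- do.call(rbind, lapply(lines[ip + seq_len(n)], num))
  ic <- grep("^CELLS", lines)[1]
  e <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cells <- do.call(rbind, lapply(lines[ic + seq_len(e)], function(s) {
    v <- num(s); as.integer(v[-1] + 1)
  }))
  point_vectors <- list()
  for (iv in grep("^VECTORS", lines)) {
    nm <- strsplit(lines[iv], "\\s+")[[1]][2]
    point_vectors[[nm]] <- do.call(rbind, lapply(lines[iv + seq_len(n)], num))
  }
  cell_scalars <- list()
  for (is in grep("^SCALARS", lines)) {
    nm <- strsplit(lines[is], "\\s+")[[1]][2]
    cell_scalars[[nm]] <- vapply(lines[is + 1L + seq_len(e)], num, numeric(1),
                                 USE.NAMES = FALSE)
  }
  list(points = pts, cells = cells,
       point_vectors = point_vectors, cell_scalars = cell_scalars)
}
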