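#' Export a mesh (and optional fields) to ASCII VTU
#'
#' Writes an XML VTK unstructured-grid file with hexahedral cells, optional
#' per-cell data (region labels are always included as integer codes) and
#' optional per-point vectors (e.g. displacements).
#'
#' @param mesh A mesh with `nodes` and `hexes`.
#' @param file Output path.
#' @param cell_data Named list of per-element numeric vectors/matrices.
#' @param point_data Named list of per-node numeric vectors/matrices.
#' @return The file path, invisibly.
#' @export
write_vtu <- function(mesh, file, cell_data = list(), point_data = list()) {
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$hexes)
  if (!is.null(mesh$region)) {
    codes <- as.integer(factor(mesh$region))
    cell_data <- c(list(region_code = codes), cell_data)
  }
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  da <- function(name, x, comps) {
    w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              name, comps))
    writeLines(paste(apply(matrix(as.numeric(t(x)), ncol = comps, byrow = TRUE),
                           1, paste, collapse = " "), collapse = "\n"), con)
    w("        </DataArray>")
  }
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w("  <UnstructuredGrid>")
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne))
  w("      <Points>")
  da("Points", mesh$nodes, 3)
  w("      </Points>")
  w("      <Cells>")
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(apply(mesh$hexes - 1L, 1, paste, collapse = " "),
                   collapse = "\n"), con)
  w("        </DataArray>")
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(ne) * 8L, collapse = " "), con)
  w("        </DataArray>")
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(12L, ne), collapse = " "), con)
  w("        </DataArray>")
  w("      </Cells>")
  if (length(cell_data)) {
    w("      <CellData>")
    for (nm in names(cell_data)) {
      x <- cell_data[[nm]]
      da(nm, x, if (is.matrix(x)) ncol(x) else 1)
    }
    w("      </CellData>")
  }
  if (length(point_data)) {
    w("      <PointData>")
    for (nm in names(point_data)) {
      x <- point_data[[nm]]
      da(nm, x, if (is.matrix(x)) ncol(x) else 1)
    }
    w("      </PointData>")
  }
  w("    </Piece>")
  w("  </UnstructuredGrid>")
  w("</VTKFile>")
  invisible(file)
}

#' Export a mesh as a plain-text finite-element input deck
#'
#' Nodes, hexahedral elements grouped by region, and node sets, in a simple
#' keyword format for cross-checking against external solvers.
#'
#' @param mesh A mesh with `nodes`, `hexes`, `region`, `node_sets`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_fe_deck <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  for (rg in unique(mesh$region)) {
    idx <- which(mesh$region == rg)
    writeLines(sprintf("*ELEMENT, TYPE=C3D8, ELSET=%s", rg), con)
    writeLines(paste0(idx, ", ", apply(mesh$hexes[idx, , drop = FALSE], 1,
                                       paste, collapse = ", ")), con)
  }
  for (nm in names(mesh$node_sets)) {
    writeLines(sprintf("*NSET, NSET=%s", nm), con)
    ids <- mesh$node_sets[[nm]]
    for (i in seq(1, length(ids), by = 12))
      writeLines(paste(ids[i:min(i + 11, length(ids))], collapse = ", "), con)
  }
  invisible(file)
}

#' Write a result table to CSV and JSON
#' @param table A data.frame.
#' @param path_base Path without extension; `.csv` and `.json` are appended.
#' @return Character vector of the two paths, invisibly.
#' @export
write_result_table <- function(table, path_base) {
  csv <- paste0(path_base, ".csv"); js <- paste0(path_base, ".json")
  utils::write.csv(table, csv, row.names = FALSE)
  jsonlite::write_json(table, js, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(csv, js))
}
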