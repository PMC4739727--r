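#' Write a hexahedral mesh with fields as legacy ASCII VTK
#'
#' Produces a VTK "UNSTRUCTURED_GRID" file readable by ParaView/VisIt, with
#' optional per-node vector data (e.g. displacement) and per-element scalar
#' data (e.g. alpha, delta-alpha, fiber force).
#'
#' @param mesh A [build_mesh()] result.
#' @param path Output `.vtk` file.
#' @param point_vectors Named list of n_nodes x 3 matrices.
#' @param cell_scalars Named list of length-n_elements numeric vectors.
#' @export
write_vtk <- function(mesh, path, point_vectors = list(),
                      cell_scalars = list()) {
  stopifnot(inherits(mesh, "hex_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("fibrogel gel mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", nn)
  writeLines(apply(mesh$nodes, 1, function(p)
    sprintf("%.10g %.10g %.10g", p[1], p[2], p[3])), con)
  w("CELLS %d %d", ne, ne * 9)
  writeLines(apply(mesh$elems - 1L, 1, function(e)
    paste(c(8L, e), collapse = " ")), con)
  w("CELL_TYPES %d", ne)
  writeLines(rep("12", ne), con) # VTK_HEXAHEDRON
  if (length(point_vectors)) {
    w("POINT_DATA %d", nn)
    for (nm in names(point_vectors)) {
      v <- point_vectors[[nm]]
      stopifnot(nrow(v) == nn, ncol(v) == 3)
      w("VECTORS %s double", nm)
      writeLines(apply(v, 1, function(p)
        sprintf("%.10g %.10g %.10g", p[1], p[2], p[3])), con)
    }
  }
  if (length(cell_scalars)) {
    w("CELL_DATA %d", ne)
    for (nm in names(cell_scalars)) {
      s <- cell_scalars[[nm]]
      stopifnot(length(s) == ne)
      w("SCALARS %s double 1", nm)
      w("LOOKUP_TABLE default")
      writeLines(sprintf("%.10g", s), con)
    }
  }
  invisible(path)
}

#' Export a compaction result to disk
#'
#' Writes the deformed-state fields as legacy VTK (`fields.vtk`: nodal
#' displacement, per-element alpha / delta-alpha / mean fiber force /
#' domain and region codes), the scalar time series as
#' `history.csv`, the solver logs as `log.txt`, and the configuration
#' (with its seed) as `config.json`.
#'
#' @param result A [run_compaction()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_compaction <- function(result, dir) {
  stopifnot(inherits(result, "compaction_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vtk(result$mesh, file.path(dir, "fields.vtk"),
            point_vectors = list(displacement = result$fields$u),
            cell_scalars = list(alpha = result$fields$alpha,
                                alpha0 = result$fields$alpha0,
                                delta_alpha = result$fields$delta_alpha,
                                fiber_force = result$fields$fiber_force,
                                cellular = as.numeric(result$labels$label == "cellular"),
                                region = as.numeric(result$regions)))
  write.csv(result$history, file.path(dir, "history.csv"), row.names = FALSE)
  cfg <- result$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_lines <- vapply(seq_along(result$logs), function(i) {
    lg <- result$logs[[i]]
    sprintf("solve %d: %d iterations, residual %s, coupling_rel %s",
            i, lg$iterations,
            paste(signif(lg$residual_history, 4), collapse = " -> "),
            format(lg$coupling_rel))
  }, character(1))
  writeLines(log_lines, file.path(dir, "log.txt"))
  invisible(dir)
}
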