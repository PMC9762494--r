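#' Export voxel fields as a legacy ASCII VTK structured-points file
#'
#' Writes scalar (and optionally vector) voxel data as VTK
#' `STRUCTURED_POINTS` for inspection in ParaView or similar viewers.
#' Accepts a [solve_stokes_flow()] solution (pressure + velocity), a label
#' array from [separate_objects()], or any 3D numeric array.
#'
#' @param x a `flow_solution`, a label/numeric 3D array, or a
#'   `voxel_volume`.
#' @param path output `.vtk` file path.
#' @param name dataset name for plain arrays.
#' @return `path`, invisibly.
#' @export
write_vtk_structured <- function(x, path, name = "values") {
  if (inherits(x, "flow_solution")) {
    d <- dim(x$pressure)
    h <- x$voxel_size_um
    con <- vtk_header(path, d, h)
    on.exit(close(con))
    writeLines(sprintf("POINT_DATA %d", prod(d)), con)
    vtk_scalars(con, "pressure_Pa", x$pressure)
    writeLines("VECTORS velocity_m_per_s double", con)
    v <- cbind(as.vector(x$velocity$x), as.vector(x$velocity$y),
               as.vector(x$velocity$z))
    v[is.na(v)] <- 0
    writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
    return(invisible(path))
  }
  a <- x
  h <- attr(x, "voxel_size_um") %||% 1
  stopifnot(length(dim(a)) == 3)
  con <- vtk_header(path, dim(a), h)
  on.exit(close(con))
  writeLines(sprintf("POINT_DATA %d", prod(dim(a))), con)
  vtk_scalars(con, name, a)
  invisible(path)
}

vtk_header <- function(path, d, h) {
  con <- file(path, open = "wt")
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "poromech voxel export",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
    sprintf("ORIGIN 0 0 0"),
    sprintf("SPACING %g %g %g", h, h, h)
  ), con)
  con
}

vtk_scalars <- function(con, name, a) {
  writeLines(sprintf("SCALARS %s double 1", name), con)
  writeLines("LOOKUP_TABLE default", con)
  v <- as.vector(a)
  v[is.na(v)] <- 0
  writeLines(as.character(v), con)
}

#' Write a characterization report as JSON
#'
#' Serializes the scalar outputs of every executed pipeline stage (the
#' [tidy.characterization_report()] table) together with the provenance
#' block.
#'
#' @param report a [run_pipeline()] result.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "characterization_report"))
  out <- list(
    provenance = report$provenance,
    values = tidy(report)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
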