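# Artifact writers: legacy-ASCII VTK for solver fields, CSV for profiles,
# JSON-lines run logs. (No VTK writer exists among the installed R
# packages, so the small legacy-format writer lives here.)

#' Write a flow-field snapshot as legacy VTK
#'
#' Writes cell-center coordinates and velocity/pressure values of one
#' stored phase as an ASCII VTK structured grid (axisymmetric tube: points
#' at (z, r) in the meridional plane) or as a point cloud (polydata) for
#' the masked planar junction.
#'
#' @param field a `flow_field`.
#' @param path output `.vtk` path.
#' @param phase stored phase index (default peak systole).
#' @export
write_flow_vtk <- function(field, path, phase = NULL) {
  if (is.null(phase)) phase <- field$peak_idx
  g <- field$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("avfcfd %s phase %d t=%.6g", g$topology, phase,
                       field$times[phase]),
               "ASCII"), con)
  if (g$topology == "axisymmetric_tube") {
    uc <- .axi_u_centers(field, phase)
    vc <- .axi_v_centers(field, phase)
    p <- matrix(field$p[, phase], g$Nz, g$Nr)
    pts <- cbind(rep(g$zc, times = g$Nr),
                 as.numeric(outer(g$R_zc, g$etac)),
                 0)
    writeLines(c("DATASET STRUCTURED_GRID",
                 sprintf("DIMENSIONS %d %d 1", g$Nz, g$Nr),
                 sprintf("POINTS %d double", nrow(pts))), con)
    utils::write.table(pts, con, row.names = FALSE, col.names = FALSE)
    writeLines(sprintf("POINT_DATA %d", nrow(pts)), con)
    writeLines(c("VECTORS velocity double"), con)
    utils::write.table(cbind(as.numeric(uc), as.numeric(vc), 0), con,
                       row.names = FALSE, col.names = FALSE)
    writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", as.numeric(p)), con)
  } else {
    meta <- field$disc_meta
    cid <- meta$cid
    sel <- which(cid > 0, arr.ind = TRUE)
    pts <- cbind(g$xc[sel[, 1]], g$yc[sel[, 2]], 0)
    p <- field$p[, phase][cid[sel]]
    writeLines(c("DATASET POLYDATA",
                 sprintf("POINTS %d double", nrow(pts))), con)
    utils::write.table(pts, con, row.names = FALSE, col.names = FALSE)
    writeLines(sprintf("POINT_DATA %d", nrow(pts)), con)
    writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", p), con)
  }
  invisible(path)
}

#' Write a centerline as VTK polyline
#'
#' @param cl a [centerline()].
#' @param path output `.vtk` path.
#' @export
write_centerline_vtk <- function(cl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(cl$points)
  writeLines(c("# vtk DataFile Version 3.0", "centerline", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  utils::write.table(cl$points, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("LINES 1 %d", n + 1), con)
  writeLines(paste(c(n, seq_len(n) - 1), collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS arc_length double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.8g", cl$s), con)
  invisible(path)
}

# JSON-lines run logger
run_logger <- function(path) {
  force(path)
  function(stage, ...) {
    rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = path, append = TRUE, sep = "")
    invisible(rec)
  }
}
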