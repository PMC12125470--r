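# Legacy-ASCII VTK export/import for gridded velocity fields and network
# centerlines (visualization plumbing; plain-text formats only).

#' Write a gridded velocity field as a legacy VTK structured-points file
#'
#' @param field A [grid_velocity_field()].
#' @param path Output path (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_vtk_structured <- function(field, path) {
  stopifnot(inherits(field, "grid_velocity_field"))
  d <- dim(field$u)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "olfnet grid velocity field",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
    sprintf("ORIGIN %.17g %.17g %.17g", field$origin[1], field$origin[2],
            field$origin[3]),
    sprintf("SPACING %.17g %.17g %.17g", field$spacing[1], field$spacing[2],
            field$spacing[3]),
    sprintf("POINT_DATA %d", prod(d)),
    "VECTORS velocity double"
  ), con)
  m <- cbind(as.vector(field$v), as.vector(field$w), as.vector(field$u))
  # VTK x-fastest ordering matches R array ordering; components written as
  # (x, y, z) = (v, w, u) with u the axial (z) component
  writeLines(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]), con)
  invisible(path)
}

#' Read a legacy VTK structured-points velocity field
#'
#' Reads files produced by [write_vtk_structured()].
#'
#' @param path Input path.
#' @return A [grid_velocity_field()].
#' @export
read_vtk_structured <- function(path) {
  lines <- readLines(path)
  grab <- function(key) {
    ln <- grep(paste0("^", key), lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(sub(key, "", ln)), "\\s+")[[1]])
  }
  d <- as.integer(grab("DIMENSIONS"))
  origin <- grab("ORIGIN")
  spacing <- grab("SPACING")
  start <- grep("^VECTORS", lines)[1] + 1L
  vals <- do.call(rbind, lapply(lines[start:(start + prod(d) - 1L)],
                                function(s) as.numeric(strsplit(s, "\\s+")[[1]])))
  grid_velocity_field(
    u = array(vals[, 3], dim = d),
    v = array(vals[, 1], dim = d),
    w = array(vals[, 2], dim = d),
    spacing = spacing, origin = origin
  )
}

#' Write network centerlines as VTK polylines
#'
#' Each segment becomes a two-point polyline along its axis starting at its
#' axial station; epithelium class is attached as cell data.
#'
#' @param network A `channel_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vtk_network <- function(network, path) {
  segs <- network$segments
  n <- nrow(segs)
  p0 <- cbind(segs$axial_start, 0, 0)
  p1 <- p0 + segs$length * cbind(segs$axis_x, segs$axis_y, segs$axis_z)
  pts <- rbind(p0, p1)
  class_code <- match(segs$epithelium,
                      c("respiratory", "olfactory", "nonabsorbing"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "olfnet channel network centerlines",
    "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d double", 2L * n)
  ), con)
  writeLines(sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3]), con)
  writeLines(sprintf("LINES %d %d", n, 3L * n), con)
  writeLines(sprintf("2 %d %d", seq_len(n) - 1L, n + seq_len(n) - 1L), con)
  writeLines(c(sprintf("CELL_DATA %d", n),
               "SCALARS epithelium_class int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", class_code), con)
  invisible(path)
}
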