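# Output writers: legacy VTK structured-points fields for ParaView/VisIt
# inspection, and CSV tables with `#`-comment header metadata.

#' Write gridded fields as a legacy VTK structured-points file
#'
#' Writes `u`, `v`, `p`, vorticity and the stream function (plus the
#' velocity as a VECTORS array) in ASCII legacy VTK format, suitable for
#' the streamline workflow of VisIt or ParaView.
#'
#' @param state `fluid_state`
#' @param path output `.vtk` file
#' @param title dataset title line
#' @return `path`, invisibly
#' @export
write_vtk_fields <- function(state, path, title = "trabflow fields") {
  g <- state$grid
  psi <- tryCatch(stream_function(state)$psi,
                  error = function(e) matrix(NA_real_, g$Nx, g$Ny))
  w <- vorticity(state)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", g$Nx, g$Ny),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.10g %.10g 1", g$h, g$h),
               sprintf("POINT_DATA %d", g$Nx * g$Ny)), con)
  scalar <- function(name, m) {
    writeLines(c(sprintf("SCALARS %s float 1", name), "LOOKUP_TABLE default"),
               con)
    # VTK structured points iterate x fastest
    writeLines(formatC(as.vector(m), format = "g", digits = 7), con)
  }
  scalar("u", state$u)
  scalar("v", state$v)
  if (!is.null(state$p)) scalar("p", state$p)
  scalar("vorticity", w)
  scalar("psi", psi)
  writeLines("VECTORS velocity float", con)
  writeLines(paste(formatC(as.vector(state$u), format = "g", digits = 7),
                   formatC(as.vector(state$v), format = "g", digits = 7),
                   "0"), con)
  invisible(path)
}

#' Write a boundary curve as a VTK polyline file
#' @param curve `boundary_curve`
#' @param path output `.vtk` file
#' @return `path`, invisibly
#' @export
write_vtk_boundary <- function(curve, path) {
  n <- nrow(curve$points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "trabflow boundary", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(paste(formatC(curve$points[, 1], format = "g", digits = 8),
                   formatC(curve$points[, 2], format = "g", digits = 8), "0"),
             con)
  writeLines(sprintf("VERTICES %d %d", n, 2 * n), con)
  writeLines(paste(1, 0:(n - 1)), con)
  invisible(path)
}

# CSV with "# key: value" header lines.
write_csv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a velocity transect as CSV (with metadata header)
#' @param transect from [velocity_transect()]
#' @param path output path
#' @param meta named list of metadata written as `# key: value` lines
#' @return `path`, invisibly
#' @export
write_transect_csv <- function(transect, path, meta = list()) {
  write_csv_meta(as.data.frame(transect), path, meta)
}

#' Read a CSV written with metadata header lines
#' @param path CSV path
#' @return data frame; metadata in attribute `"meta"`
#' @export
read_csv_meta <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  df <- read.csv(text = paste(ln[!startsWith(ln, "#")], collapse = "\n"))
  meta <- list()
  for (l in hdr) {
    kv <- sub("^# *", "", l)
    i <- regexpr(":", kv)
    if (i > 0) meta[[trimws(substr(kv, 1, i - 1))]] <- trimws(substring(kv, i + 1))
  }
  attr(df, "meta") <- meta
  df
}
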