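# Legacy-VTK ASCII polydata I/O for medial surfaces, carrying the radius
# function and per-vertex normals as point-data arrays.

#' Write a medial surface to legacy VTK polydata
#'
#' Vertices, triangles, the per-vertex `radius` scalar and `normal`
#' vectors are stored; coordinates are written with enough precision that
#' a read-back reproduces them within 1e-6 mm.
#'
#' @param surface a valid [medial_surface()].
#' @param path output `.vtk` path.
#' @export
write_mesh <- function(surface, path) {
  stopifnot(inherits(surface, "medial_surface"))
  v <- surface$vertices; tr <- surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tractsheet medial surface",
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  writeLines(apply(v, 1, function(p) paste(sprintf("%.10g", p),
                                           collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4 * nrow(tr)), con)
  writeLines(apply(tr - 1L, 1, function(t_) paste(c(3L, t_),
                                                  collapse = " ")), con)
  writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
  writeLines(c("SCALARS radius float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.10g", surface$radius), con)
  writeLines("NORMALS normal float", con)
  writeLines(apply(surface$normals, 1,
                   function(p) paste(sprintf("%.10g", p), collapse = " ")),
             con)
  invisible(path)
}

#' Read a medial surface from legacy VTK polydata
#'
#' @param path a `.vtk` file written by [write_mesh()] (or any ASCII
#'   legacy polydata with triangle cells and `radius` / `normal` point
#'   data).
#' @return A [medial_surface()].
#' @export
read_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1])) {
    ts_stop("format_error", "%s is not a legacy VTK file", path)
  }
  if (toupper(trimws(lines[3])) != "ASCII") {
    ts_stop("format_error", "only ASCII legacy VTK is supported")
  }
  toks <- scan(text = paste(lines[-(1:3)], collapse = "\n"), what = "character",
               quiet = TRUE)
  i <- 1L
  expect <- function(word) {
    if (toupper(toks[i]) != word) {
      ts_stop("format_error", "expected %s at token %d, found %s",
              word, i, toks[i])
    }
    i <<- i + 1L
  }
  expect("DATASET"); expect("POLYDATA")
  expect("POINTS")
  np <- as.integer(toks[i]); i <- i + 2L  # count, dtype
  v <- matrix(as.numeric(toks[i:(i + 3 * np - 1)]), ncol = 3, byrow = TRUE)
  i <- i + 3L * np
  expect("POLYGONS")
  nt <- as.integer(toks[i]); ntok <- as.integer(toks[i + 1]); i <- i + 2L
  cells <- as.integer(toks[i:(i + ntok - 1)]); i <- i + ntok
  tr <- matrix(NA_integer_, nt, 3)
  j <- 1L
  for (ci in seq_len(nt)) {
    k <- cells[j]
    if (k != 3L) {
      ts_stop("format_error", "cell %d has %d vertices; only triangles", ci, k)
    }
    tr[ci, ] <- cells[(j + 1):(j + 3)] + 1L
    j <- j + k + 1L
  }
  expect("POINT_DATA")
  i <- i + 1L  # count
  radius <- NULL; normals <- NULL
  while (i <= length(toks)) {
    kind <- toupper(toks[i])
    if (kind == "SCALARS") {
      name <- toks[i + 1]; i <- i + 3L
      if (grepl("^[0-9]+$", toks[i])) i <- i + 1L  # optional numComp
      if (toupper(toks[i]) == "LOOKUP_TABLE") i <- i + 2L
      vals <- as.numeric(toks[i:(i + np - 1)]); i <- i + np
      if (name == "radius") radius <- vals
    } else if (kind == "NORMALS") {
      i <- i + 3L
      normals <- matrix(as.numeric(toks[i:(i + 3 * np - 1)]), ncol = 3,
                        byrow = TRUE)
      i <- i + 3L * np
    } else {
      ts_stop("format_error", "unsupported point-data section '%s'", toks[i])
    }
  }
  if (is.null(radius) || is.null(normals)) {
    ts_stop("format_error",
            "mesh lacks the 'radius' scalar or 'normal' vectors")
  }
  medial_surface(v, tr, unit_rows(normals), radius)
}
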