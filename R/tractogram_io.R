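# Readers and writers for streamline files: MRtrix TCK and TrackVis TRK.
# Points are always expressed in world mm in memory; the TRK voxel-mm
# corner-origin convention is converted on the way in and out.

detect_tract_format <- function(path) {
  if (!file.exists(path)) {
    ts_stop("format_error", "no such tractogram file: %s", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 13)
  if (length(magic) >= 13 &&
      identical(magic, charToRaw("mrtrix tracks"))) return("tck")
  if (length(magic) >= 5 &&
      identical(magic[1:5], charToRaw("TRACK"))) return("trk")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tck", "trk")) return(ext)
  ts_stop("format_error", "cannot identify %s as TCK or TRK", path)
}

#' Read a tractogram (TCK or TRK, auto-detected)
#'
#' @param path file path; format detected from magic bytes, falling back
#'   to the extension.
#' @return A [tractogram()] with points in world mm.
#' @export
read_tractogram <- function(path) {
  switch(detect_tract_format(path),
         tck = read_tck(path),
         trk = read_trk(path))
}

#' Write a tractogram to TCK or TRK
#'
#' @param tg a [tractogram()].
#' @param path output path ending in `.tck` or `.trk`.
#' @param affine voxel-to-world matrix of the reference grid; required for
#'   TRK (whose on-disk coordinates are voxel-mm with corner origin).
#' @param dims reference grid size, required for TRK.
#' @export
write_tractogram <- function(tg, path, affine = diag(4), dims = c(1, 1, 1)) {
  stopifnot(inherits(tg, "tractogram"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = write_tck(tg, path),
         trk = write_trk(tg, path, affine, dims),
         ts_stop("format_error", "unsupported tractogram extension '%s'", ext))
}

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  offset <- NA_integer_
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) {
      ts_stop("format_error", "TCK header of %s has no END marker", path)
    }
    header <- c(header, line)
    if (grepl("^file:", line)) {
      offset <- as.integer(sub("^file:\\s*\\.\\s*", "", line))
    }
    if (line == "END") break
  }
  if (header[1] != "mrtrix tracks") {
    ts_stop("format_error", "%s is not a TCK file", path)
  }
  dt <- grep("^datatype:", header, value = TRUE)
  if (length(dt) && !grepl("Float32LE", dt[1])) {
    ts_stop("format_error", "unsupported TCK datatype: %s", dt[1])
  }
  if (is.na(offset)) {
    ts_stop("format_error", "TCK header lacks a file offset")
  }
  sz <- file.info(path)$size
  seek(con, offset)
  nbytes <- sz - offset
  if (nbytes %% 12 != 0) {
    ts_stop("format_error",
            "truncated TCK stream in %s at byte offset %d", path, sz)
  }
  vals <- readBin(con, "numeric", n = nbytes / 4, size = 4,
                  endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  streamlines <- list()
  cur <- NULL
  ended <- FALSE
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (all(is.nan(p))) {
      if (!is.null(cur)) {
        streamlines[[length(streamlines) + 1L]] <- do.call(rbind, cur)
        cur <- NULL
      }
    } else if (all(is.infinite(p))) {
      ended <- TRUE
      break
    } else {
      cur <- c(cur, list(p))
    }
  }
  if (!ended) {
    ts_stop("format_error",
            "truncated TCK stream in %s at byte offset %d (no EOF sentinel)",
            path, sz)
  }
  tractogram(streamlines, provenance = list(source = path, format = "tck"))
}

write_tck <- function(tg, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- c("mrtrix tracks",
             "datatype: Float32LE",
             sprintf("count: %d", length(tg$streamlines)))
  # The offset line length depends on the offset itself; fix by padding.
  base_len <- sum(nchar(lines) + 1L) + nchar("END") + 1L
  offset <- base_len + nchar("file: . ") + 6L + 1L
  lines <- c(lines, sprintf("file: . %06d", offset), "END")
  writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con,
            eos = NULL, useBytes = TRUE)
  for (s in tg$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname read_tractogram
#' @export
read_trk <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1000) {
    ts_stop("format_error",
            "truncated TRK file %s (%d bytes < 1000-byte header)",
            path, if (is.na(sz)) 0L else sz)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", n = 6)
  if (rawToChar(id[1:5]) != "TRACK") {
    ts_stop("format_error", "%s lacks the TRACK magic", path)
  }
  readBin(con, "integer", n = 3, size = 2)  # dim
  voxel_size <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # origin
  n_scalars <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  readBin(con, "raw", n = 200)
  n_props <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  readBin(con, "raw", n = 200)
  vox2ras <- matrix(readBin(con, "numeric", n = 16, size = 4,
                            endian = "little"), 4, 4, byrow = TRUE)
  readBin(con, "raw", n = 444 + 4 + 4 + 24 + 2 + 6)
  n_count <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  version <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (hdr_size != 1000L) {
    ts_stop("format_error", "unexpected TRK header size %d", hdr_size)
  }
  if (version >= 2 && all(vox2ras == 0)) {
    ts_stop("format_error", "TRK v2 file with zero vox_to_ras matrix")
  }
  if (all(vox2ras == 0)) vox2ras <- diag(4)
  streamlines <- list()
  pos <- 1000
  repeat {
    np <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (length(np) == 0) break
    pos <- pos + 4
    need <- np * (3 + n_scalars) + n_props
    vals <- readBin(con, "numeric", n = need, size = 4, endian = "little")
    if (length(vals) < need) {
      ts_stop("format_error",
              "truncated TRK stream in %s at byte offset %d",
              path, pos + 4 * length(vals))
    }
    pos <- pos + 4 * need
    m <- matrix(vals[seq_len(np * (3 + n_scalars))],
                ncol = 3 + n_scalars, byrow = TRUE)
    voxmm <- m[, 1:3, drop = FALSE]
    vox <- sweep(voxmm, 2, voxel_size, `/`) - 0.5
    streamlines[[length(streamlines) + 1L]] <- voxel_to_world(vox, vox2ras)
  }
  if (n_count > 0 && length(streamlines) != n_count) {
    ts_stop("format_error",
            "TRK %s declares %d streamlines but holds %d (truncated at byte %d)",
            path, n_count, length(streamlines), pos)
  }
  tractogram(streamlines, provenance = list(source = path, format = "trk"))
}

write_trk <- function(tg, path, affine, dims) {
  check_affine(affine)
  voxel_size <- voxel_sizes(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(dims), con, size = 2, endian = "little")
  writeBin(voxel_size, con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")  # origin
  writeBin(0L, con, size = 2, endian = "little")          # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")          # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                  # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(raw(1), con)
  writeBin(raw(4), con)                                    # pad2
  writeBin(numeric(6), con, size = 4, endian = "little")   # orientation
  writeBin(raw(2), con)                                    # pad1
  writeBin(raw(6), con)                                    # invert/swap
  writeBin(length(tg$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")           # version
  writeBin(1000L, con, size = 4, endian = "little")
  for (s in tg$streamlines) {
    vox <- world_to_voxel(s, affine)
    voxmm <- sweep(vox + 0.5, 2, voxel_size, `*`)
    writeBin(nrow(s), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
  invisible(path)
}
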