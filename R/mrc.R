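#' Read an MRC2014 raster
#'
#' Reads a 2D image or 3D volume from an MRC2014 file. Data are returned as
#' [micrograph()] (2D, default), [probability_map()] or [label_map()] (2D, on
#' request) or [volume()] (3D). The physical pixel size is taken from the
#' header cell dimensions divided by the sampling grid (`CELLA / MX`).
#'
#' Only the common voxel modes are supported: 0 (int8), 1 (int16), 2
#' (float32) and 6 (uint16). Files are written in mode 2.
#'
#' @param path Path to an existing MRC file.
#' @param as For 2D data, how to interpret the raster: `"micrograph"`
#'   (default), `"probability_map"` or `"label_map"`. Ignored for 3D data.
#' @return A raster object; see [rasters].
#' @seealso [write_mrc()]
#' @export
read_mrc <- function(path,
                     as = c("micrograph", "probability_map", "label_map")) {
  as <- match.arg(as)
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  if (file.size(path) < 1024) abort_format("MRC header truncated")
  con <- file(path, "rb")
  on.exit(close(con))

  nx <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  mode <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", 3L, size = 4L, endian = "little") # nxstart..
  m_grid <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  cella <- readBin(con, "double", 3L, size = 4L, endian = "little")
  seek(con, 208)
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(substr(magic, 1, 3), "MAP")) {
    abort_format("not an MRC2014 file (missing MAP magic)")
  }
  if (any(nx < 1L)) abort_format("MRC header declares empty dimensions")

  n <- prod(as.double(nx))
  seek(con, 1024)
  vec <- switch(as.character(mode),
    "0" = as.double(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    "1" = as.double(readBin(con, "integer", n, size = 2L, signed = TRUE,
                            endian = "little")),
    "2" = readBin(con, "double", n, size = 4L, endian = "little"),
    "6" = as.double(readBin(con, "integer", n, size = 2L, signed = FALSE,
                            endian = "little")),
    abort_format(sprintf("unsupported MRC mode %d", mode))
  )
  if (length(vec) < n) abort_format("MRC data block truncated")
  if (!all(is.finite(vec))) abort_validation("MRC data contains non-finite voxels")

  px <- if (m_grid[1] > 0 && cella[1] > 0) cella[1] / m_grid[1] else 1

  if (nx[3] == 1L) {
    mat <- t(matrix(vec, nx[1], nx[2]))
    nm <- sub("\\.[^.]*$", "", basename(path))
    switch(as,
      micrograph = micrograph(mat, pixel_size = px, name = nm),
      probability_map = probability_map(mat, source = nm),
      label_map = label_map(mat, source = nm)
    )
  } else {
    volume(aperm(array(vec, nx), c(3, 2, 1)), voxel_size = px)
  }
}

#' Write a raster to an MRC2014 file
#'
#' Writes a 2D raster or 3D volume as MRC2014 mode 2 (float32), little
#' endian, with the cell dimensions encoding the physical pixel size.
#'
#' @param x A [micrograph()], [volume()], [probability_map()], [label_map()]
#'   or plain numeric matrix/3D array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path) {
  d <- raster_data(x)
  if (!all(is.finite(d))) abort_validation("raster contains non-finite values")
  px <- attr(x, "pixel_size") %||% attr(x, "voxel_size") %||% 1

  if (is.matrix(d)) {
    dims <- c(ncol(d), nrow(d), 1L)          # nx, ny, nz
    vec <- as.vector(t(d))                   # x fastest
  } else if (length(dim(d)) == 3L) {
    dims <- dim(d)[c(3, 2, 1)]
    vec <- as.vector(aperm(d, c(3, 2, 1)))
  } else {
    abort_shape("only 2D matrices and 3D arrays can be written to MRC")
  }

  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort_io(conditionMessage(e)),
                  warning = function(w) abort_io(conditionMessage(w)))
  on.exit(close(con))

  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")

  wi(dims)                                   # NX NY NZ
  wi(2L)                                     # MODE float32
  wi(c(0L, 0L, 0L))                          # N*START
  wi(dims)                                   # MX MY MZ
  wf(px * dims)                              # CELLA (Angstrom)
  wf(c(90, 90, 90))                          # CELLB
  wi(c(1L, 2L, 3L))                          # MAPC MAPR MAPS
  wf(c(min(d), max(d), mean(d)))             # DMIN DMAX DMEAN
  wi(c(0L, 0L))                              # ISPG NSYMBT
  wi(rep(0L, 2))                             # EXTRA words 25-26
  writeChar("MRCO", con, 4L, eos = NULL)     # EXTTYP
  wi(20140L)                                 # NVERSION
  wi(rep(0L, 21))                            # EXTRA words 29-49
  wf(c(0, 0, 0))                             # ORIGIN
  writeChar("MAP ", con, 4L, eos = NULL)     # magic
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little endian
  wf(if (length(d) > 1) stats::sd(d) else 0) # RMS
  wi(0L)                                     # NLABL
  writeBin(raw(800L), con)                   # labels
  writeBin(vec, con, size = 4L, endian = "little")
  invisible(path)
}
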