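#' Raster containers for micrographs, volumes and per-pixel maps
#'
#' Micrographs and probability/label maps are 2D numeric matrices indexed
#' `[row, col]` = `[y + 1, x + 1]` for the 0-based pixel coordinate `(x, y)`
#' with origin at the top-left pixel. Volumes are 3D arrays indexed
#' `[z + 1, y + 1, x + 1]`. Constructors attach physical scale and identity
#' as attributes and validate the invariants of each type.
#'
#' @param data Numeric matrix (2D types) or 3D array (`volume()`).
#' @param pixel_size,voxel_size Physical sampling in Angstrom per pixel/voxel
#'   (> 0).
#' @param name,source Identifier string: the micrograph's own name, or for
#'   derived maps the identifier of the micrograph they belong to.
#' @return An object of class `"micrograph"`, `"volume"`,
#'   `"probability_map"` or `"label_map"`; the underlying numeric data is the
#'   object itself (matrix/array subclass).
#' @examples
#' m <- micrograph(matrix(rnorm(64), 8, 8), pixel_size = 1.32, name = "mic1")
#' p <- probability_map(matrix(runif(64), 8, 8), source = "mic1")
#' @name rasters
NULL

#' @rdname rasters
#' @export
micrograph <- function(data, pixel_size = 1, name = "micrograph") {
  data <- as_matrix2d(data, "micrograph")
  check_finite(data, "micrograph")
  check_pixel_size(pixel_size)
  structure(data, pixel_size = pixel_size, name = name, class = "micrograph")
}

#' @rdname rasters
#' @export
volume <- function(data, voxel_size = 1) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_shape("`data` must be a 3D array (z, y, x)")
  }
  data <- ensure_double(data)
  check_finite(data, "volume")
  check_pixel_size(voxel_size)
  structure(data, voxel_size = voxel_size, class = "volume")
}

#' @rdname rasters
#' @export
probability_map <- function(data, source = "") {
  data <- as_matrix2d(data, "probability map")
  check_finite(data, "probability map")
  if (any(data < 0 | data > 1)) {
    abort_validation("probability map values must lie in [0, 1]")
  }
  structure(data, source = source, class = "probability_map")
}

#' @rdname rasters
#' @export
label_map <- function(data, source = "") {
  data <- as_matrix2d(data, "label map")
  check_finite(data, "label map")
  if (!all(data %in% c(0, 1))) {
    abort_validation("label map values must be exactly 0 or 1")
  }
  structure(data, source = source, class = "label_map")
}

#' Strip raster class and attributes, returning plain numeric data
#' @param x A raster object (or plain matrix/array).
#' @return The underlying matrix or array.
#' @export
raster_data <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(x))
  a
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf(
    "<micrograph '%s'> %d x %d px, %.3g A/px, range [%.3g, %.3g]\n",
    attr(x, "name") %||% "", nrow(x), ncol(x), attr(x, "pixel_size") %||% NA,
    min(x), max(x)
  ))
  invisible(x)
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<volume> %d x %d x %d voxels (z,y,x), %.3g A/voxel\n",
    d[1], d[2], d[3], attr(x, "voxel_size") %||% NA
  ))
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf(
    "<probability_map of '%s'> %d x %d px, range [%.3g, %.3g]\n",
    attr(x, "source") %||% "", nrow(x), ncol(x), min(x), max(x)
  ))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf(
    "<label_map of '%s'> %d x %d px, %d foreground px\n",
    attr(x, "source") %||% "", nrow(x), ncol(x), sum(x)
  ))
  invisible(x)
}

# ---- internal helpers --------------------------------------------------

ensure_double <- function(x) {
  if (!is.double(x)) storage.mode(x) <- "double"
  x
}

as_matrix2d <- function(data, what) {
  if (is.matrix(data)) return(ensure_double(data))
  if (is.array(data) && length(dim(data)) == 2L) {
    return(ensure_double(matrix(data, dim(data)[1], dim(data)[2])))
  }
  abort_shape(sprintf("%s data must be a 2D numeric matrix", what))
}

check_finite <- function(data, what) {
  if (!all(is.finite(data))) {
    abort_validation(sprintf("%s contains non-finite values", what))
  }
  invisible(TRUE)
}

check_pixel_size <- function(ps) {
  if (!is.numeric(ps) || length(ps) != 1L || !is.finite(ps) || ps <= 0) {
    abort_validation("pixel/voxel size must be a single positive number")
  }
  invisible(TRUE)
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "micropick_error_validation")
}
abort_shape <- function(msg) {
  rlang::abort(msg, class = "micropick_error_shape")
}
abort_format <- function(msg) {
  rlang::abort(msg, class = "micropick_error_format")
}
abort_domain <- function(msg) {
  rlang::abort(msg, class = "micropick_error_domain")
}
abort_usage <- function(msg) {
  rlang::abort(msg, class = "micropick_error_usage")
}
abort_io <- function(msg) {
  rlang::abort(msg, class = "micropick_error_io")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
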