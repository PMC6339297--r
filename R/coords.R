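#' Particle pick sets
#'
#' A pick set is a tibble of particle centers with one row per pick and
#' columns `x`, `y` (0-based pixel coordinates of the particle center,
#' `x` = column, `y` = row), `score` and `box_size` (the particle side length
#' `s` in pixels). Rows are kept sorted by descending score and duplicate
#' centers are rejected.
#'
#' @param x,y Numeric vectors of center coordinates.
#' @param score Numeric scores (recycled).
#' @param box_size Box side length in pixels (recycled, >= 1).
#' @param micrograph Identifier of the source micrograph.
#' @return A tibble of class `"pick_set"`.
#' @examples
#' pick_set(x = c(10, 40), y = c(12, 44), score = c(0.9, 0.8), box_size = 20)
#' @export
pick_set <- function(x = numeric(), y = numeric(), score = 0, box_size = 1,
                     micrograph = "") {
  n <- length(x)
  if (length(y) != n) abort_validation("`x` and `y` must have equal length")
  tb <- tibble::tibble(
    x = as.double(x), y = as.double(y),
    score = rep_len(as.double(score), n),
    box_size = rep_len(as.double(box_size), n)
  )
  if (any(!is.finite(tb$score))) abort_validation("pick scores must be finite")
  if (any(tb$box_size < 1)) abort_validation("box_size must be >= 1")
  if (anyDuplicated(tb[c("x", "y")])) {
    abort_validation("duplicate pick centers are not allowed")
  }
  tb <- dplyr::arrange(tb, dplyr::desc(score))
  new_pick_set(tb, micrograph)
}

new_pick_set <- function(tb, micrograph = "") {
  structure(tb, micrograph = micrograph,
            class = c("pick_set", class(tibble::tibble())))
}

#' Read particle coordinates
#'
#' Parses particle coordinate files in one of three dialects and converts
#' every record to the internal 0-based particle-center convention:
#'
#' * `"box"`: EMAN box files, one `x_corner y_corner width height` line per
#'   particle; the stored top-left corner is converted via
#'   `center = corner + floor(box / 2)`.
#' * `"coord"`: plain two-column whitespace `x_center y_center` files.
#' * `"star"`: a STAR particles loop restricted to `rlnCoordinateX/Y`
#'   (optionally `rlnAutopickFigureOfMerit` for scores).
#'
#' @param path File to read.
#' @param dialect One of `"box"`, `"coord"`, `"star"`.
#' @param box_size Box size to assign when the dialect does not store one
#'   (`"coord"`, `"star"`).
#' @return A [pick_set()].
#' @export
read_coords <- function(path, dialect = c("box", "coord", "star"),
                        box_size = 1) {
  dialect <- check_dialect(dialect)
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))

  if (dialect == "star") {
    loop <- parse_star_loop(path)
    if (nrow(loop) == 0) return(pick_set())
    need <- c("rlnCoordinateX", "rlnCoordinateY")
    if (!all(need %in% names(loop))) {
      abort_format("STAR loop lacks rlnCoordinateX/rlnCoordinateY")
    }
    score <- if ("rlnAutopickFigureOfMerit" %in% names(loop)) {
      loop$rlnAutopickFigureOfMerit
    } else 0
    return(pick_set(loop$rlnCoordinateX, loop$rlnCoordinateY,
                    score = score, box_size = box_size))
  }

  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(pick_set())
  fields <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(fields)
  want <- if (dialect == "box") 4L else 2L
  if (any(ncols != want)) {
    abort_format(sprintf("expected %d columns in every %s line", want, dialect))
  }
  m <- matrix(suppressWarnings(as.double(unlist(fields))),
              ncol = want, byrow = TRUE)
  if (any(!is.finite(m))) abort_format("non-numeric coordinate field")

  if (dialect == "box") {
    pick_set(m[, 1] + floor(m[, 3] / 2), m[, 2] + floor(m[, 4] / 2),
             box_size = m[, 3])
  } else {
    pick_set(m[, 1], m[, 2], box_size = box_size)
  }
}

#' Write particle coordinates
#'
#' Inverse of [read_coords()]: centers are written back in the conventions of
#' the chosen dialect so that a write/read round trip preserves them exactly.
#'
#' @param picks A [pick_set()].
#' @param path Output file.
#' @param dialect One of `"box"`, `"coord"`, `"star"`.
#' @return `path`, invisibly.
#' @export
write_coords <- function(picks, path, dialect = c("box", "coord", "star")) {
  dialect <- check_dialect(dialect)
  lines <- switch(dialect,
    box = sprintf("%g\t%g\t%g\t%g",
                  picks$x - floor(picks$box_size / 2),
                  picks$y - floor(picks$box_size / 2),
                  picks$box_size, picks$box_size),
    coord = sprintf("%g\t%g", picks$x, picks$y),
    star = c(
      "", "data_particles", "", "loop_",
      "_rlnCoordinateX #1",
      "_rlnCoordinateY #2",
      "_rlnAutopickFigureOfMerit #3",
      sprintf("%g\t%g\t%g", picks$x, picks$y, picks$score)
    )
  )
  writeLines(lines, path)
  invisible(path)
}

check_dialect <- function(dialect) {
  dialect <- dialect[1]
  if (!dialect %in% c("box", "coord", "star")) {
    abort_usage(sprintf("unknown coordinate dialect '%s'", dialect))
  }
  dialect
}

# Minimal STAR reader: first data_ block's loop_, columns named by their
# _rln tags. Covers the particles subset this package consumes, nothing more.
parse_star_loop <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  i <- which(startsWith(lines, "loop_"))[1]
  if (is.na(i)) abort_format("no loop_ block in STAR file")
  tags <- character()
  j <- i + 1
  while (j <= length(lines) && startsWith(lines[j], "_")) {
    tags <- c(tags, sub("^_", "", sub("\\s+#\\d+$", "", lines[j])))
    j <- j + 1
  }
  if (length(tags) == 0) abort_format("STAR loop declares no columns")
  rows <- character()
  while (j <= length(lines) && nzchar(lines[j]) &&
         !startsWith(lines[j], "data_")) {
    rows <- c(rows, lines[j])
    j <- j + 1
  }
  if (length(rows) == 0) {
    return(stats::setNames(
      as.data.frame(rep(list(numeric()), length(tags))), tags))
  }
  fields <- strsplit(rows, "\\s+")
  if (any(lengths(fields) != length(tags))) {
    abort_format("STAR loop row has wrong number of fields")
  }
  m <- matrix(unlist(fields), ncol = length(tags), byrow = TRUE)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- tags
  for (k in seq_along(out)) {
    num <- suppressWarnings(as.double(out[[k]]))
    if (!anyNA(num)) out[[k]] <- num
  }
  out
}

#' Orientation tables for label generation
#'
#' One row per particle: micrograph identifier, particle center `(cx, cy)`
#' on the micrograph (0-based pixels), refined Euler angles `rot`, `tilt`,
#' `psi` in degrees (intrinsic ZYZ) and refinement translations `dx`, `dy`
#' in pixels.
#'
#' @param micrograph,cx,cy,rot,tilt,psi,dx,dy Column vectors (angles in
#'   degrees, coordinates and translations in pixels).
#' @return A tibble of class `"orientation_tbl"`.
#' @export
orientation_records <- function(micrograph, cx, cy, rot = 0, tilt = 0,
                                psi = 0, dx = 0, dy = 0) {
  n <- length(cx)
  tb <- tibble::tibble(
    micrograph = rep_len(as.character(micrograph), n),
    cx = as.double(cx), cy = as.double(cy),
    rot = rep_len(as.double(rot), n), tilt = rep_len(as.double(tilt), n),
    psi = rep_len(as.double(psi), n),
    dx = rep_len(as.double(dx), n), dy = rep_len(as.double(dy), n)
  )
  if (!all(is.finite(as.matrix(tb[-1])))) {
    abort_validation("orientation records must be finite")
  }
  class(tb) <- c("orientation_tbl", class(tibble::tibble()))
  tb
}

#' Read an orientation table from STAR or TSV
#'
#' STAR input uses the RELION particle tags `rlnCoordinateX/Y`,
#' `rlnAngleRot/Tilt/Psi`, `rlnOriginX/Y` and optionally
#' `rlnMicrographName`; TSV input uses columns named as in
#' [orientation_records()].
#'
#' @param path File to read.
#' @param format `"star"` or `"tsv"`.
#' @param micrograph Fallback micrograph identifier when the file does not
#'   name one.
#' @return An orientation tibble; see [orientation_records()].
#' @export
read_orientations <- function(path, format = c("star", "tsv"),
                              micrograph = "micrograph") {
  format <- match.arg(format)
  if (format == "star") {
    loop <- parse_star_loop(path)
    get <- function(tag, default = 0) {
      if (tag %in% names(loop)) loop[[tag]] else default
    }
    if (!all(c("rlnCoordinateX", "rlnCoordinateY") %in% names(loop))) {
      abort_format("STAR loop lacks rlnCoordinateX/rlnCoordinateY")
    }
    orientation_records(
      micrograph = get("rlnMicrographName", micrograph),
      cx = loop$rlnCoordinateX, cy = loop$rlnCoordinateY,
      rot = get("rlnAngleRot"), tilt = get("rlnAngleTilt"),
      psi = get("rlnAnglePsi"),
      dx = get("rlnOriginX"), dy = get("rlnOriginY")
    )
  } else {
    tb <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("micrograph", "cx", "cy", "rot", "tilt", "psi", "dx", "dy")
    if (!all(need %in% names(tb))) {
      abort_format("TSV orientation table lacks required columns")
    }
    orientation_records(tb$micrograph, tb$cx, tb$cy, tb$rot, tb$tilt,
                        tb$psi, tb$dx, tb$dy)
  }
}

#' Write an orientation table as TSV
#' @param records An orientation tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orientations <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
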