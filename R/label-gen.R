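#' Project a volume along z at given Euler angles
#'
#' Rotates the volume about its center by the intrinsic ZYZ Euler angles
#' `(rot, tilt, psi)` (degrees, RELION-style) using trilinear interpolation
#' and sums along the z axis, producing the `box x box` reprojection image
#' of a particle in that orientation. At the identity rotation the sampling
#' grid coincides with the voxel grid, so the result equals the direct
#' z-sum exactly.
#'
#' @param V A [volume()] (array indexed `[z, y, x]`).
#' @param rot,tilt,psi Euler angles in degrees.
#' @param box Output side length in pixels (<= every volume dimension).
#' @return A `box x box` numeric matrix.
#' @export
project_volume <- function(V, rot = 0, tilt = 0, psi = 0, box = min(dim(V))) {
  d <- dim(raster_data(V))
  if (box > min(d)) abort_shape("box exceeds the volume dimensions")
  if (!all(is.finite(c(rot, tilt, psi)))) {
    abort_validation("Euler angles must be finite")
  }
  A <- raster_data(V)
  D <- d[1]; Hv <- d[2]; Wv <- d[3]

  R <- euler_zyz(rot, tilt, psi)
  half <- (box - 1) / 2
  xs <- (0:(box - 1)) - half
  zs <- (0:(D - 1)) - (D - 1) / 2
  # sample points ordered y-fastest, then x, then z (matches array fill)
  pts <- cbind(
    x = rep(xs, each = box, times = D),
    y = rep(xs, times = box * D),
    z = rep(zs, each = box * box)
  )
  src <- pts %*% R          # rotate the sampling grid into the volume frame
  vals <- trilinear_sample(
    A,
    z = src[, 3] + (D - 1) / 2,
    y = src[, 2] + (Hv - 1) / 2,
    x = src[, 1] + (Wv - 1) / 2
  )
  rowSums(matrix(vals, box * box, D))[seq_len(box * box)] |>
    matrix(box, box)
}

# Intrinsic ZYZ rotation matrix, angles in degrees. Columns act on (x, y, z)
# row vectors via p %*% R, mapping projection-frame points into the volume.
euler_zyz <- function(rot, tilt, psi) {
  rz <- function(a) {
    c <- cos(a); s <- sin(a)
    matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  }
  ry <- function(a) {
    c <- cos(a); s <- sin(a)
    matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, 3, byrow = TRUE)
  }
  d2r <- pi / 180
  rz(rot * d2r) %*% ry(tilt * d2r) %*% rz(psi * d2r)
}

# Vectorized trilinear interpolation of a [z, y, x] array at fractional
# 0-based coordinates; points outside the array contribute 0.
trilinear_sample <- function(A, z, y, x) {
  d <- dim(A)
  z0 <- floor(z); y0 <- floor(y); x0 <- floor(x)
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  out <- numeric(length(z))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    zi <- z0 + cz; yi <- y0 + cy; xi <- x0 + cx
    w <- (if (cz) fz else 1 - fz) * (if (cy) fy else 1 - fy) *
         (if (cx) fx else 1 - fx)
    ok <- zi >= 0 & zi < d[1] & yi >= 0 & yi < d[2] & xi >= 0 & xi < d[3] &
          w > 0
    if (any(ok)) {
      lin <- zi[ok] + d[1] * (yi[ok] + d[2] * xi[ok]) + 1
      out[ok] <- out[ok] + w[ok] * A[lin]
    }
  }
  out
}

#' Shift image content by a (possibly fractional) translation
#'
#' Shifts the image by `(dx, dy)` pixels (content moves toward +x/+y);
#' integer shifts are exact, fractional shifts use bilinear interpolation,
#' and vacated regions are zero-filled.
#'
#' @param img Numeric matrix.
#' @param dx,dy Shift in pixels (columns, rows).
#' @return Matrix of the same shape.
#' @export
apply_translation <- function(img, dx, dy) {
  if (dx == 0 && dy == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  xq <- rep(0:(w - 1), each = h) - dx
  yq <- rep(0:(h - 1), times = w) - dy
  x0 <- floor(xq); y0 <- floor(yq)
  fx <- xq - x0; fy <- yq - y0
  out <- numeric(h * w)
  for (cy in 0:1) for (cx in 0:1) {
    yi <- y0 + cy; xi <- x0 + cx
    wgt <- (if (cy) fy else 1 - fy) * (if (cx) fx else 1 - fx)
    ok <- yi >= 0 & yi < h & xi >= 0 & xi < w & wgt > 0
    if (any(ok)) {
      out[ok] <- out[ok] + wgt[ok] * img[yi[ok] + h * xi[ok] + 1]
    }
  }
  matrix(out, h, w)
}

#' Binarize a reprojection tile
#'
#' Thresholds a (noise-free) reprojection with Otsu's method computed on the
#' tile's own histogram, yielding the particle's segmentation mask. A
#' constant tile has no foreground and maps to an all-zero mask.
#'
#' @param img Numeric matrix with finite values.
#' @param source Identifier carried on the returned mask.
#' @return A [label_map()] of the same shape.
#' @export
binarize_projection <- function(img, source = "") {
  check_finite(img, "projection")
  rg <- range(img)
  if (diff(rg) == 0) {
    return(label_map(matrix(0, nrow(img), ncol(img)), source = source))
  }
  thr <- EBImage::otsu(img, range = rg, levels = 256)
  label_map((img > thr) * 1, source = source)
}

#' Composite particle tiles into a micrograph label map
#'
#' Pastes each binary tile centered at its particle coordinate into an
#' `H x W` map, combining overlaps by logical OR; tile parts beyond the
#' micrograph edges are clipped. The top-left corner of a `b x b` tile
#' centered at `(cx, cy)` is `(cx - floor(b/2), cy - floor(b/2))`.
#'
#' @param tiles List of tiles, each a list with elements `mask` (binary
#'   matrix) and `cx`, `cy` (0-based center on the micrograph).
#' @param H,W Micrograph dimensions.
#' @param source Identifier carried on the returned map.
#' @return A [label_map()] of shape `H x W`.
#' @export
composite_labels <- function(tiles, H, W, source = "") {
  out <- matrix(0, H, W)
  for (t in tiles) {
    m <- raster_data(t$mask)
    b_h <- nrow(m); b_w <- ncol(m)
    top <- round(t$cy) - floor(b_h / 2)   # 0-based row of tile row 1
    left <- round(t$cx) - floor(b_w / 2)
    if (top + b_h - 1 < 0 || top > H - 1 || left + b_w - 1 < 0 ||
        left > W - 1) next
    rows <- max(0, top):min(H - 1, top + b_h - 1)
    cols <- max(0, left):min(W - 1, left + b_w - 1)
    out[rows + 1, cols + 1] <- pmax(out[rows + 1, cols + 1],
                                    m[rows - top + 1, cols - left + 1])
  }
  label_map(out, source = source)
}

#' Generate a segmentation label map for one micrograph
#'
#' Runs the reprojection labeling chain for every orientation record of a
#' micrograph: project the reconstruction at the particle's refined Euler
#' angles, shift by its refinement translation, binarize (Otsu), and
#' composite all tiles at the particle coordinates.
#'
#' @param V A [volume()] (the reconstruction).
#' @param records An [orientation_records()] tibble (rows for one
#'   micrograph).
#' @param H,W Micrograph dimensions in pixels.
#' @param box Reprojection tile side in pixels.
#' @param translation_sign `+1` (default) shifts the reprojection by
#'   `(+dx, +dy)` to align it with the particle as extracted; `-1` flips
#'   the convention for tables whose origins are stored with the opposite
#'   sign.
#' @param binarize_first Binarize before (TRUE) instead of after (default)
#'   the translation adjustment.
#' @return A [label_map()].
#' @export
generate_label_map <- function(V, records, H, W, box,
                               translation_sign = 1,
                               binarize_first = FALSE) {
  tiles <- purrr::pmap(
    records[c("rot", "tilt", "psi", "dx", "dy", "cx", "cy")],
    function(rot, tilt, psi, dx, dy, cx, cy) {
      img <- project_volume(V, rot, tilt, psi, box)
      if (binarize_first) {
        img <- raster_data(binarize_projection(img))
        img <- apply_translation(img, translation_sign * dx,
                                 translation_sign * dy)
        mask <- label_map((img >= 0.5) * 1)
      } else {
        img <- apply_translation(img, translation_sign * dx,
                                 translation_sign * dy)
        mask <- binarize_projection(img)
      }
      list(mask = mask, cx = cx, cy = cy)
    }
  )
  composite_labels(tiles, H, W,
                   source = if (nrow(records)) records$micrograph[1] else "")
}

#' Sample aligned (micrograph, label) training windows
#'
#' Builds the per-micrograph label maps with [generate_label_map()] and
#' samples `n_windows` aligned square windows per micrograph at seeded
#' uniform offsets, the extraction unit used to train a segmentation
#' network.
#'
#' @param V A [volume()].
#' @param records An [orientation_records()] tibble (column `micrograph`
#'   selects the rows for each micrograph).
#' @param micrographs Named list of [micrograph()] objects; names must match
#'   `records$micrograph`.
#' @param tile Window side in pixels (<= micrograph dimensions).
#' @param box Reprojection tile side in pixels.
#' @param n_windows Windows per micrograph.
#' @param seed Integer seed controlling the window offsets.
#' @param ... Passed to [generate_label_map()].
#' @return A tibble with columns `micrograph`, `x0`, `y0` (0-based window
#'   origin) and list-columns `image`, `label` holding the aligned windows.
#' @export
generate_label_dataset <- function(V, records, micrographs, tile, box,
                                   n_windows = 8, seed = 1, ...) {
  ids <- names(micrographs)
  if (is.null(ids)) abort_usage("`micrographs` must be a named list")
  withr::with_seed(seed, {
    purrr::map_dfr(ids, function(id) {
      mic <- micrographs[[id]]
      H <- nrow(mic); W <- ncol(mic)
      if (tile > H || tile > W) abort_shape("tile larger than micrograph")
      lab <- generate_label_map(V, records[records$micrograph == id, ],
                                H, W, box, ...)
      x0 <- sample.int(W - tile + 1L, n_windows, replace = TRUE) - 1L
      y0 <- sample.int(H - tile + 1L, n_windows, replace = TRUE) - 1L
      tibble::tibble(
        micrograph = id, x0 = x0, y0 = y0,
        image = purrr::map2(x0, y0, function(x, y) {
          raster_data(mic)[(y + 1):(y + tile), (x + 1):(x + tile)]
        }),
        label = purrr::map2(x0, y0, function(x, y) {
          raster_data(lab)[(y + 1):(y + tile), (x + 1):(x + tile)]
        })
      )
    })
  })
}
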