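#' Picker configuration
#'
#' Collects the tunable parameters of the grid-based local-maximum picker.
#' The grid side is `g = floor(s / 2)` for particle size `s`, so that two
#' accepted picks can overlap by at most `s^2 / 4` pixels; the same bound
#' motivates the default minimum separation `s / 2`.
#'
#' @param particle_size Particle side length `s` in pixels (>= 1).
#' @param score_threshold Candidates scoring below this are dropped
#'   (default 0.6).
#' @param max_picks Keep at most this many highest-scoring picks
#'   (default 500).
#' @param sigma Standard deviation of the Gaussian scoring kernel in pixels
#'   (default `s / 4`, placing essentially all kernel mass inside the box).
#' @param search_radius Half-side of the square local-maximum search window
#'   in pixels (default: the grid side `g`, so a candidate can always leave
#'   its starting cell).
#' @param max_iters Iteration cap for the local-maximum ascent (default 100).
#' @param min_separation Minimum Euclidean distance between accepted picks
#'   (default `s / 2`).
#' @return A list of class `"picker_config"`.
#' @export
picker_config <- function(particle_size, score_threshold = 0.6,
                          max_picks = 500, sigma = particle_size / 4,
                          search_radius = NULL, max_iters = 100,
                          min_separation = particle_size / 2) {
  if (particle_size < 1) abort_validation("particle_size must be >= 1")
  if (score_threshold < 0 || score_threshold > 1) {
    abort_validation("score_threshold must lie in [0, 1]")
  }
  if (max_picks < 1 || sigma <= 0 || max_iters < 1 || min_separation <= 0) {
    abort_validation("picker parameters must be positive")
  }
  g <- max(1L, floor(particle_size / 2))
  structure(list(
    particle_size = particle_size, score_threshold = score_threshold,
    max_picks = max_picks, sigma = sigma,
    search_radius = search_radius %||% g, max_iters = max_iters,
    min_separation = min_separation, grid = g
  ), class = "picker_config")
}

#' Gaussian candidate-scoring kernel
#'
#' Builds the normalized Gaussian weight lattice `W[x, y] proportional to
#' exp(-(x^2 + y^2) / (2 sigma^2))` used to score a candidate particle
#' centered on a pixel: center pixels get more influence, which reduces
#' interference from neighboring particles. The lattice is centered at 0,
#' so its side is `s` for odd `s` and `s + 1` for even `s` (the taps run
#' from `-s/2` to `s/2`); weights sum to 1.
#'
#' @param s Particle size in pixels.
#' @param sigma Gaussian standard deviation in pixels (default `s / 4`).
#' @return A numeric matrix of class `"gaussian_kernel"` with attributes
#'   `particle_size` and `sigma`.
#' @export
build_kernel <- function(s, sigma = s / 4) {
  if (s < 1) abort_validation("s must be >= 1")
  if (sigma <= 0) abort_validation("sigma must be > 0")
  half <- floor(s / 2)
  ax <- -half:half
  W <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  W <- W / sum(W)
  structure(W, particle_size = s, sigma = sigma, class = "gaussian_kernel")
}

#' Score every pixel as a candidate center
#'
#' Correlates the probability map with the Gaussian kernel so that each
#' pixel holds the score of the candidate particle centered on it:
#' `score(m, n) = sum_{x,y} W[x, y] * V[m + x, n + y]`. The map is
#' zero-padded (background probability 0), which suppresses edge picks; the
#' output has the same shape as the input.
#'
#' @param P A [probability_map()] or numeric matrix.
#' @param kernel A [build_kernel()] matrix.
#' @return Numeric matrix of class `"score_map"`.
#' @export
score_map <- function(P, kernel) {
  V <- raster_data(P)
  W <- raster_data(kernel)
  if (nrow(W) > nrow(V) || ncol(W) > ncol(V)) {
    abort_shape("kernel larger than map")
  }
  # EBImage::filter2 is FFT convolution with the flipped kernel; the
  # Gaussian lattice is symmetric, so it equals the correlation above.
  S <- EBImage::filter2(V, W, boundary = 0)
  S <- matrix(as.numeric(S), nrow(V), ncol(V))
  if (min(V) >= 0 && max(V) <= 1) S <- pmin(pmax(S, 0), 1)
  structure(S, class = "score_map")
}

#' Grid specification for candidate initialization
#'
#' Tiles an `H x W` map with cells of side `g = floor(s / 2)` (ceiling
#' division, so the last row/column of cells may be partial): one candidate
#' will be drawn per cell. For a 4096 x 4096 map with `g = 100` this gives
#' `41 * 41 = 1681` candidates instead of one per pixel (16,777,216).
#'
#' @param H,W Map dimensions in pixels.
#' @param particle_size Particle side `s`; the grid side defaults to
#'   `floor(s / 2)`.
#' @param g Grid cell side, overriding `particle_size`.
#' @return A list of class `"grid_spec"` with elements `g`, `nx`, `ny` and
#'   `n_candidates = nx * ny`.
#' @export
grid_spec <- function(H, W, particle_size = NULL, g = NULL) {
  if (is.null(g)) {
    if (is.null(particle_size)) abort_usage("give either particle_size or g")
    g <- max(1L, floor(particle_size / 2))
  }
  if (g < 1) abort_validation("grid side must be >= 1")
  nx <- ceiling(W / g)
  ny <- ceiling(H / g)
  structure(list(g = g, nx = nx, ny = ny, n_candidates = nx * ny),
            class = "grid_spec")
}

#' One maximum candidate per grid cell
#'
#' Scans each grid cell of the score map and emits a candidate at the
#' cell's maximum; ties are broken by the lowest row-major linear index
#' (`y * W + x`). The number of candidates is exactly `grid$nx * grid$ny`.
#'
#' @param S A [score_map()] or numeric matrix.
#' @param grid A [grid_spec()].
#' @return A tibble with columns `x`, `y` (0-based) and `score`.
#' @export
init_grid_candidates <- function(S, grid) {
  S <- raster_data(S)
  H <- nrow(S); W <- ncol(S)
  g <- grid$g
  xs <- numeric(grid$nx * grid$ny)
  ys <- numeric(length(xs))
  sc <- numeric(length(xs))
  i <- 0L
  for (cy in seq_len(grid$ny)) {
    rows <- ((cy - 1L) * g + 1L):min(cy * g, H)
    for (cx in seq_len(grid$nx)) {
      cols <- ((cx - 1L) * g + 1L):min(cx * g, W)
      sub <- S[rows, cols, drop = FALSE]
      k <- row_major_argmax(sub)
      i <- i + 1L
      ys[i] <- rows[k[1]] - 1L
      xs[i] <- cols[k[2]] - 1L
      sc[i] <- sub[k[1], k[2]]
    }
  }
  tibble::tibble(x = xs, y = ys, score = sc)
}

# (row, col) 1-based position of the maximum, ties broken by the lowest
# row-major linear index of the matrix.
row_major_argmax <- function(m) {
  k <- which.max(t(m)) - 1L
  c(k %/% ncol(m) + 1L, k %% ncol(m) + 1L)
}

#' Iterative local-maximum ascent
#'
#' Each candidate repeatedly jumps to the maximum of the score map inside
#' the square window of half-side `radius` centered on its current
#' position, until the position is a fixed point or `max_iters` is reached.
#' Candidates are independent of one another; scores never decrease across
#' iterations. Ties take the lowest row-major index in the window.
#'
#' @param S A [score_map()] or numeric matrix.
#' @param candidates Tibble with columns `x`, `y` (0-based), as produced by
#'   [init_grid_candidates()].
#' @param radius Search window half-side in pixels (>= 1).
#' @param max_iters Iteration cap (>= 1).
#' @return The candidate tibble with updated `x`, `y`, `score` plus
#'   `iterations` and `converged` columns.
#' @export
local_max_ascend <- function(S, candidates, radius, max_iters = 100) {
  if (radius < 1) abort_validation("radius must be >= 1")
  S <- raster_data(S)
  H <- nrow(S); W <- ncol(S)
  n <- nrow(candidates)
  x <- candidates$x; y <- candidates$y
  iters <- integer(n); conv <- logical(n); sc <- numeric(n)
  for (i in seq_len(n)) {
    cx <- x[i]; cy <- y[i]
    for (it in seq_len(max_iters)) {
      rows <- max(0, cy - radius):min(H - 1, cy + radius)
      cols <- max(0, cx - radius):min(W - 1, cx + radius)
      sub <- S[rows + 1, cols + 1, drop = FALSE]
      k <- row_major_argmax(sub)
      ny <- rows[k[1]]; nx <- cols[k[2]]
      iters[i] <- it
      if (nx == cx && ny == cy) { conv[i] <- TRUE; break }
      cx <- nx; cy <- ny
    }
    x[i] <- cx; y[i] <- cy; sc[i] <- S[cy + 1, cx + 1]
  }
  tibble::tibble(x = x, y = y, score = sc, iterations = iters,
                 converged = conv)
}

#' Greedy non-maximum suppression of candidates
#'
#' Sorts candidates by descending score (ties by lowest row-major position)
#' and accepts each one only if its Euclidean distance to every previously
#' accepted candidate is at least `min_separation`. Candidates that
#' co-converged to the same local maximum collapse to one survivor.
#'
#' @param candidates Tibble with columns `x`, `y`, `score`.
#' @param min_separation Minimum pairwise distance in pixels (> 0).
#' @return The surviving rows, sorted by descending score.
#' @export
deduplicate <- function(candidates, min_separation) {
  if (min_separation <= 0) abort_validation("min_separation must be > 0")
  n <- nrow(candidates)
  if (n == 0) return(candidates)
  ord <- order(-candidates$score, candidates$y, candidates$x)
  x <- candidates$x[ord]; y <- candidates$y[ord]
  keep <- logical(n)
  ax <- numeric(0); ay <- numeric(0)
  for (i in seq_len(n)) {
    if (length(ax) == 0 ||
        all((ax - x[i])^2 + (ay - y[i])^2 >= min_separation^2)) {
      keep[i] <- TRUE
      ax <- c(ax, x[i]); ay <- c(ay, y[i])
    }
  }
  candidates[ord[keep], , drop = FALSE]
}

#' Threshold, optional re-scoring hook, and pick cap
#'
#' Drops candidates scoring below `score_threshold` (default 0.6), applies
#' an optional pluggable scoring hook (the slot where a trained
#' false-positive classifier would sit: any function mapping the candidate
#' tibble to a new score vector) followed by re-thresholding, and keeps at
#' most `max_picks` (default 500) highest-scoring picks.
#'
#' @param candidates Deduplicated candidate tibble (`x`, `y`, `score`).
#' @param config A [picker_config()].
#' @param scorer Optional function `f(candidates) -> numeric scores`.
#' @return A [pick_set()] sorted by descending score, `box_size` set to the
#'   configured particle size.
#' @export
filter_picks <- function(candidates, config, scorer = NULL) {
  keep <- candidates[candidates$score >= config$score_threshold, ,
                     drop = FALSE]
  if (!is.null(scorer) && nrow(keep) > 0) {
    keep$score <- as.double(scorer(keep))
    keep <- keep[keep$score >= config$score_threshold, , drop = FALSE]
  }
  keep <- keep[order(-keep$score, keep$y, keep$x), , drop = FALSE]
  if (nrow(keep) > config$max_picks) {
    keep <- keep[seq_len(config$max_picks), , drop = FALSE]
  }
  pick_set(keep$x, keep$y, score = keep$score,
           box_size = config$particle_size)
}

#' Pick particles from a probability density map
#'
#' The full grid-based local-maximum pipeline: Gaussian candidate scoring
#' ([score_map()]), one candidate per grid cell ([init_grid_candidates()]),
#' iterative local-maximum ascent ([local_max_ascend()]), greedy
#' non-maximum suppression ([deduplicate()]) and threshold/cap filtering
#' ([filter_picks()]). Deterministic for fixed inputs.
#'
#' @param P A [probability_map()] (or numeric matrix of per-pixel particle
#'   probabilities).
#' @param config A [picker_config()].
#' @param scorer Optional candidate re-scoring hook; see [filter_picks()].
#' @param verbose Log per-stage candidate counts to stderr.
#' @return A [pick_set()].
#' @examples
#' p <- matrix(0, 64, 64)
#' p[20:24, 20:24] <- 1; p[40:44, 48:52] <- 1
#' picks <- pick_particles(probability_map(p), picker_config(11))
#' @export
pick_particles <- function(P, config, scorer = NULL, verbose = FALSE) {
  S <- score_map(P, build_kernel(config$particle_size, config$sigma))
  grid <- grid_spec(nrow(S), ncol(S), g = config$grid)
  cands <- init_grid_candidates(S, grid)
  if (verbose) {
    message(sprintf("grid %dx%d cells (g=%d): %d candidates",
                    grid$ny, grid$nx, grid$g, nrow(cands)))
  }
  cands <- local_max_ascend(S, cands, radius = config$search_radius,
                            max_iters = config$max_iters)
  dedup <- deduplicate(cands, config$min_separation)
  if (verbose) {
    message(sprintf("after ascent (median %d iters) and NMS: %d candidates",
                    stats::median(cands$iterations), nrow(dedup)))
  }
  picks <- filter_picks(dedup, config, scorer = scorer)
  attr(picks, "micrograph") <- attr(P, "source") %||% ""
  if (verbose) message(sprintf("final picks: %d", nrow(picks)))
  picks
}
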