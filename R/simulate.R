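#' Simulation configuration
#'
#' Parameters of the synthetic micrograph generator. The defaults describe
#' the standard test condition used throughout the package: 25 particles of
#' box size 32 px on a 512 x 512 micrograph with pairwise separation at
#' least twice the box size, and additive white Gaussian noise at 0 dB
#' (noise energy equal to signal energy).
#'
#' @param mic_shape `(H, W)` micrograph dimensions in pixels.
#' @param particle_radius Radius of the toy particle's bounding sphere in
#'   voxels/pixels.
#' @param box_size Particle box side `s` in pixels.
#' @param n_particles Number of particles per micrograph.
#' @param min_separation Minimum pairwise center distance in pixels
#'   (default `2 * box_size`: non-overlapping particles).
#' @param snr_db Target signal-to-noise ratio in dB,
#'   `10 * log10(sum(signal^2) / sum(noise^2))`; `NULL` disables noise.
#' @param max_shift Refinement-style translations `dx`, `dy` are drawn
#'   uniformly from `[-max_shift, max_shift]` pixels.
#' @param blur_sigma Gaussian blur, in pixels, applied to the ground-truth
#'   mask to emulate a segmentation network's soft probability output.
#' @param volume_shape `(D, H, W)` of the toy reference volume.
#' @param seed Integer seed; a fixed seed makes the whole pipeline
#'   bit-reproducible.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(mic_shape = c(512, 512), particle_radius = 12,
                       box_size = 32, n_particles = 25,
                       min_separation = 2 * box_size, snr_db = 0,
                       max_shift = 2, blur_sigma = 2,
                       volume_shape = rep(box_size, 3), seed = 1) {
  if (any(volume_shape < 8)) abort_validation("volume_shape must be >= 8^3")
  if (box_size > min(volume_shape)) {
    abort_validation("box_size must fit inside volume_shape")
  }
  if (2 * particle_radius > box_size) {
    abort_validation("particle must fit inside its box")
  }
  structure(list(
    mic_shape = mic_shape, particle_radius = particle_radius,
    box_size = box_size, n_particles = n_particles,
    min_separation = min_separation, snr_db = snr_db,
    max_shift = max_shift, blur_sigma = blur_sigma,
    volume_shape = volume_shape, seed = seed
  ), class = "sim_config")
}

#' Toy reference volume
#'
#' A seeded union of 1-5 soft-edged spheres/ellipsoids near the volume
#' center: the primary lobe is a sphere of the configured particle radius,
#' secondary lobes are smaller and offset but kept inside the primary
#' radius, so the whole particle fits a ball of `particle_radius`. Values
#' lie in [0, 1] (soft edge about 1.5 voxels wide).
#'
#' @param cfg A [sim_config()].
#' @param n_lobes Number of lobes; default draws 1-5 from the seeded RNG.
#' @return A [volume()].
#' @export
make_toy_volume <- function(cfg, n_lobes = NULL) {
  withr::with_seed(cfg$seed, {
    d <- cfg$volume_shape
    r0 <- cfg$particle_radius
    if (is.null(n_lobes)) n_lobes <- sample.int(5L, 1L)
    zc <- (d[1] - 1) / 2; yc <- (d[2] - 1) / 2; xc <- (d[3] - 1) / 2
    zz <- rep(0:(d[1] - 1), times = d[2] * d[3]) - zc
    yy <- rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]) - yc
    xx <- rep(0:(d[3] - 1), each = d[1] * d[2]) - xc
    edge <- 1.5
    soft_ball <- function(cz, cy, cx, r, ax = c(1, 1, 1)) {
      dist <- sqrt(((zz - cz) / ax[1])^2 + ((yy - cy) / ax[2])^2 +
                   ((xx - cx) / ax[3])^2)
      pmin(pmax((r - dist) / edge + 0.5, 0), 1)
    }
    v <- soft_ball(0, 0, 0, r0)
    if (n_lobes > 1) {
      for (i in seq_len(n_lobes - 1)) {
        r <- stats::runif(1, 0.25, 0.45) * r0
        off <- stats::runif(3, -1, 1)
        off <- off / max(1, sqrt(sum(off^2))) * (r0 - r) * 0.8
        ax <- stats::runif(3, 0.7, 1.3)
        v <- pmax(v, soft_ball(off[1], off[2], off[3], r, ax))
      }
    }
    volume(array(v, d))
  })
}

#' Place particles on the micrograph
#'
#' Seeded rejection sampling of integer particle centers: all pairwise distances at
#' least `min_separation`, all centers at least `max(particle_radius,
#' box_size / 2)` from every edge. Each placement gets uniform random Euler
#' angles (`tilt` drawn uniform in `cos(tilt)`, i.e. uniform over
#' orientations) and small uniform translations.
#'
#' @param cfg A [sim_config()].
#' @param micrograph_id Identifier used in the orientation table.
#' @return An [orientation_records()] tibble with one row per particle.
#' @export
place_particles <- function(cfg, micrograph_id = "sim") {
  H <- cfg$mic_shape[1]; W <- cfg$mic_shape[2]
  margin <- max(cfg$particle_radius, cfg$box_size / 2)
  if (cfg$n_particles * cfg$min_separation^2 >= H * W) {
    abort_domain("packing infeasible: too many particles for the area")
  }
  withr::with_seed(cfg$seed + 1L, {
    xs <- numeric(0); ys <- numeric(0)
    attempts <- 0L
    while (length(xs) < cfg$n_particles) {
      attempts <- attempts + 1L
      if (attempts > 1000L * cfg$n_particles) {
        abort_domain("packing infeasible after bounded attempts")
      }
      x <- sample(ceiling(margin):floor(W - 1 - margin), 1L)
      y <- sample(ceiling(margin):floor(H - 1 - margin), 1L)
      if (length(xs) == 0 ||
          all((xs - x)^2 + (ys - y)^2 >= cfg$min_separation^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    n <- cfg$n_particles
    orientation_records(
      micrograph = micrograph_id,
      cx = xs, cy = ys,
      rot = stats::runif(n, 0, 360),
      tilt = acos(stats::runif(n, -1, 1)) * 180 / pi,
      psi = stats::runif(n, 0, 360),
      dx = stats::runif(n, -cfg$max_shift, cfg$max_shift),
      dy = stats::runif(n, -cfg$max_shift, cfg$max_shift)
    )
  })
}

#' Render the noise-free micrograph and its ground truth
#'
#' Projects the reference volume at each placement's Euler angles, applies
#' its translation, and additively pastes the projections at the particle
#' centers; the ground-truth mask is the OR-composite of the binarized
#' projections and the coordinate table matches the placements exactly.
#'
#' @param V A [volume()].
#' @param placements An [orientation_records()] tibble from
#'   [place_particles()].
#' @param cfg A [sim_config()].
#' @return A list of class `"ground_truth"` with elements `clean`
#'   ([micrograph()]), `mask` ([label_map()]), `coords` ([pick_set()]) and
#'   `orientations`.
#' @export
render_clean <- function(V, placements, cfg) {
  H <- cfg$mic_shape[1]; W <- cfg$mic_shape[2]
  b <- cfg$box_size
  clean <- matrix(0, H, W)
  tiles <- vector("list", nrow(placements))
  for (i in seq_len(nrow(placements))) {
    r <- placements[i, ]
    img <- project_volume(V, r$rot, r$tilt, r$psi, b)
    img <- apply_translation(img, r$dx, r$dy)
    top <- round(r$cy) - floor(b / 2); left <- round(r$cx) - floor(b / 2)
    rows <- max(0, top):min(H - 1, top + b - 1)
    cols <- max(0, left):min(W - 1, left + b - 1)
    clean[rows + 1, cols + 1] <- clean[rows + 1, cols + 1] +
      img[rows - top + 1, cols - left + 1]
    tiles[[i]] <- list(mask = binarize_projection(img), cx = r$cx, cy = r$cy)
  }
  id <- if (nrow(placements)) placements$micrograph[1] else "sim"
  structure(list(
    clean = micrograph(clean, name = id),
    mask = composite_labels(tiles, H, W, source = id),
    coords = pick_set(placements$cx, placements$cy, score = 1,
                      box_size = b, micrograph = id),
    orientations = placements
  ), class = "ground_truth")
}

#' Add white Gaussian noise at an exact target SNR
#'
#' Draws a seeded white Gaussian noise field and scales it in closed form
#' so that the measured ratio `10 * log10(sum(clean^2) / sum(noise^2))`
#' equals the target exactly (up to floating point).
#'
#' @param clean A [micrograph()] with nonzero signal energy.
#' @param snr_db Target SNR in dB.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return A noisy [micrograph()] of the same shape.
#' @export
add_noise_to_snr <- function(clean, snr_db, seed = NULL) {
  f <- raster_data(clean)
  sig <- sum(f^2)
  if (sig == 0) abort_domain("clean image has zero signal energy")
  draw <- function() stats::rnorm(length(f))
  e <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  e <- e * sqrt(sig / 10^(snr_db / 10) / sum(e^2))
  micrograph(f + matrix(e, nrow(f), ncol(f)),
             pixel_size = attr(clean, "pixel_size") %||% 1,
             name = attr(clean, "name") %||% "noisy")
}

#' Reference probability map from ground truth
#'
#' Gaussian-blurs the ground-truth mask and rescales it to [0, 1], a
#' noise-free stand-in for the soft per-pixel output of a segmentation
#' network; `blur_sigma = 0` returns the mask itself.
#'
#' @param truth A `ground_truth` (from [render_clean()]) or a
#'   [label_map()].
#' @param blur_sigma Blur standard deviation in pixels (>= 0).
#' @return A [probability_map()].
#' @export
reference_probability_map <- function(truth, blur_sigma = 2) {
  mask <- if (inherits(truth, "ground_truth")) truth$mask else truth
  if (blur_sigma < 0) abort_validation("blur_sigma must be >= 0")
  m <- raster_data(mask) * 1.0
  if (blur_sigma > 0) {
    m <- EBImage::gblur(m, sigma = blur_sigma)
    m <- matrix(as.numeric(m), nrow(m), ncol(m))
  }
  if (max(m) > 0) m <- m / max(m)
  probability_map(pmin(pmax(m, 0), 1),
                  source = attr(mask, "source") %||% "")
}

#' Simulate a complete micrograph with ground truth
#'
#' Runs the whole generator under one seeded RNG stream, in order: toy
#' volume, particle placement, clean rendering with masks/coordinates,
#' noise at the target SNR, and the reference probability map.
#'
#' @param cfg A [sim_config()].
#' @param micrograph_id Identifier for the simulated micrograph.
#' @return A list of class `"sim_result"`: `micrograph` (noisy), `clean`,
#'   `mask`, `probmap`, `coords`, `orientations`, `volume`, `config`.
#' @examples
#' sim <- simulate_micrograph(sim_config(mic_shape = c(128, 128),
#'                                       n_particles = 3, seed = 7))
#' nrow(sim$coords)
#' @export
simulate_micrograph <- function(cfg = sim_config(), micrograph_id = "sim") {
  V <- make_toy_volume(cfg)
  placements <- place_particles(cfg, micrograph_id)
  truth <- render_clean(V, placements, cfg)
  noisy <- if (is.null(cfg$snr_db)) {
    truth$clean
  } else {
    add_noise_to_snr(truth$clean, cfg$snr_db, seed = cfg$seed + 2L)
  }
  probmap <- reference_probability_map(truth, cfg$blur_sigma)
  structure(list(
    micrograph = noisy, clean = truth$clean, mask = truth$mask,
    probmap = probmap, coords = truth$coords,
    orientations = truth$orientations, volume = V, config = cfg
  ), class = "sim_result")
}
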