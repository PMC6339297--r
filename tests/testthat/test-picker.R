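test_that("the scoring kernel is a normalized centered Gaussian", {
  expect_equal(raster_data(build_kernel(1, 1)), matrix(1, 1, 1))
  for (s in c(3, 8, 15)) {
    expect_equal(sum(build_kernel(s, s / 4)), 1, tolerance = 1e-12)
  }
  # s = 3, sigma = 1: closed-form 9-term lattice, then normalized
  g <- exp(-outer((-1:1)^2, (-1:1)^2, "+") / 2)
  expect_equal(raster_data(build_kernel(3, 1)), g / sum(g), tolerance = 1e-14)
  k <- raster_data(build_kernel(9, 2))
  expect_identical(k, k[9:1, ]) # symmetric
  expect_equal(which.max(k), 41L) # center maximal
  # even particle size uses the odd lattice spanning -s/2..s/2
  expect_equal(dim(raster_data(build_kernel(4, 1))), c(5L, 5L))
})

test_that("score maps match the brute-force correlation oracle", {
  expect_equal(max(abs(score_map(matrix(0, 9, 9), build_kernel(3, 1)))), 0)
  ones <- score_map(matrix(1, 11, 11), build_kernel(3, 1))
  expect_equal(ones[3:9, 3:9], matrix(1, 7, 7), tolerance = 1e-12)

  P <- matrix(0, 7, 7); P[4, 4] <- 1
  K <- build_kernel(3, 1)
  expect_equal(unclass(score_map(P, K)),
               oracle_score_map(P, raster_data(K)), tolerance = 1e-12,
               ignore_attr = TRUE)

  set.seed(12)
  for (rep in 1:5) {
    P <- matrix(runif(32 * 32), 32, 32)
    K <- build_kernel(sample(c(3, 5, 7), 1), runif(1, 0.5, 2))
    expect_equal(unclass(score_map(P, K)),
                 oracle_score_map(P, raster_data(K)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_error(score_map(matrix(0, 2, 2), build_kernel(9, 2)),
               class = "micropick_error_shape")
})

test_that("grid candidate counts follow ceiling division", {
  g <- grid_spec(4096, 4096, g = 100)
  expect_equal(c(g$nx, g$ny, g$n_candidates), c(41, 41, 1681))
  expect_equal(grid_spec(10, 10, particle_size = 64)$n_candidates, 1)
  set.seed(13)
  for (rep in 1:20) {
    H <- sample(1:40, 1); W <- sample(1:40, 1); gg <- sample(1:12, 1)
    expect_equal(grid_spec(H, W, g = gg)$n_candidates,
                 ceiling(H / gg) * ceiling(W / gg))
  }
})

test_that("per-cell argmax equals the exhaustive scan with row-major ties", {
  set.seed(14)
  S <- matrix(runif(100), 10, 10)
  got <- init_grid_candidates(S, grid_spec(10, 10, g = 3))
  expect_equal(as.data.frame(got), oracle_cell_argmax(S, 3),
               ignore_attr = TRUE)
  # ties inside a cell go to the lowest row-major index
  Tie <- matrix(1, 4, 4)
  got <- init_grid_candidates(Tie, grid_spec(4, 4, g = 4))
  expect_equal(c(got$x, got$y), c(0, 0))
  small <- init_grid_candidates(matrix(c(1, 3, 2, 0), 2, 2),
                                grid_spec(2, 2, g = 5))
  expect_equal(nrow(small), 1)
  expect_equal(small$score, 3)
})

test_that("local-maximum ascent climbs, terminates and breaks ties row-major", {
  ramp <- outer(1:12, 1:12, "+") * 1.0      # increases toward bottom-right
  start <- tibble::tibble(x = 0, y = 0, score = ramp[1, 1])
  out <- local_max_ascend(ramp, start, radius = 2)
  expect_equal(c(out$x, out$y), c(11, 11))
  expect_true(out$converged)

  S <- matrix(0, 9, 9); S[5, 5] <- 1
  at_max <- local_max_ascend(S, tibble::tibble(x = 4, y = 4), radius = 3)
  expect_equal(c(at_max$x, at_max$y, at_max$iterations), c(4, 4, 1))

  plateau <- matrix(1, 7, 7)
  out <- local_max_ascend(plateau, tibble::tibble(x = 6, y = 6), radius = 2)
  expect_equal(c(out$x, out$y), c(0, 0))    # walks to lowest row-major pixel
})

test_that("ascent never decreases scores and respects the iteration cap", {
  set.seed(15)
  S <- matrix(runif(900), 30, 30)
  init <- init_grid_candidates(S, grid_spec(30, 30, g = 5))
  out <- local_max_ascend(S, init, radius = 5, max_iters = 100)
  expect_true(all(out$score >= init$score))
  expect_true(all(out$iterations <= 100))
  expect_true(all(out$converged))
})

test_that("greedy NMS matches the reference suppression", {
  two <- tibble::tibble(x = c(5, 5), y = c(5, 5), score = c(0.5, 0.9))
  expect_equal(nrow(deduplicate(two, 3)), 1)
  near <- tibble::tibble(x = c(10, 11), y = c(10, 10), score = c(0.9, 0.8))
  kept <- deduplicate(near, 50)
  expect_equal(kept$score, 0.9)
  set.seed(16)
  for (rep in 1:5) {
    df <- tibble::tibble(x = runif(20, 0, 40), y = runif(20, 0, 40),
                         score = runif(20))
    mine <- deduplicate(df, 8)
    ref <- oracle_nms(as.data.frame(df), 8)
    expect_equal(mine$x, ref$x)
    expect_equal(mine$score, ref$score)
  }
})

test_that("filtering applies the 0.6 threshold, the hook and the 500 cap", {
  cfg <- picker_config(10)
  expect_equal(nrow(filter_picks(tibble::tibble(x = numeric(),
                                                y = numeric(),
                                                score = numeric()), cfg)), 0)
  three <- tibble::tibble(x = 1:3, y = 1:3, score = c(0.9, 0.7, 0.5))
  expect_equal(nrow(filter_picks(three, cfg)), 2)

  many <- tibble::tibble(x = seq_len(600) * 20, y = rep(1, 600),
                         score = runif(600, 0.61, 1))
  capped <- filter_picks(many, cfg)
  expect_equal(nrow(capped), 500)
  expect_equal(capped$score, sort(many$score, decreasing = TRUE)[1:500])

  # the pluggable hook re-scores and re-filters (classifier slot)
  hook <- function(c) ifelse(c$x < 40, 0, c$score)
  expect_equal(nrow(filter_picks(three, cfg, scorer = hook)), 0)
})

test_that("pick_particles recovers a lattice of Gaussian blobs exactly once each", {
  s <- 8
  H <- 12 * s
  P <- matrix(0, H, H)
  centers <- expand.grid(cx = c(16, 48, 80), cy = c(16, 48, 80))
  xs <- matrix(rep(0:(H - 1), each = H), H, H)
  ys <- matrix(rep(0:(H - 1), times = H), H, H)
  for (i in seq_len(nrow(centers))) {
    P <- pmax(P, exp(-((xs - centers$cx[i])^2 + (ys - centers$cy[i])^2) /
                       (2 * (s / 3)^2)))
  }
  picks <- pick_particles(probability_map(P), picker_config(s))
  expect_equal(nrow(picks), 9)
  m <- match_picks(picks, pick_set(centers$cx, centers$cy), s / 4)
  expect_equal(m$TP, 9)

  expect_equal(nrow(pick_particles(probability_map(matrix(0, 64, 64)),
                                   picker_config(s))), 0)
  again <- pick_particles(probability_map(P), picker_config(s))
  expect_identical(as.data.frame(picks), as.data.frame(again))
})

test_that("accepted picks respect the s^2/4 overlap bound", {
  sim <- tiny_sim(seed = 17, n = 6, mic = 256)
  s <- sim$config$box_size
  picks <- pick_particles(sim$probmap, picker_config(s))
  expect_gt(nrow(picks), 0)
  if (nrow(picks) > 1) {
    pr <- utils::combn(nrow(picks), 2)
    for (k in seq_len(ncol(pr))) {
      i <- pr[1, k]; j <- pr[2, k]
      dx <- abs(picks$x[i] - picks$x[j]); dy <- abs(picks$y[i] - picks$y[j])
      expect_gte(sqrt(dx^2 + dy^2), s / 2)
      overlap <- max(0, s - dx) * max(0, s - dy)
      expect_lte(overlap, s^2 / 4 + 1e-9)
    }
  }
})
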