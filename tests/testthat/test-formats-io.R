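test_that("MRC round trip preserves 2D rasters, pixel size and map types", {
  m <- micrograph(matrix(0, 4, 4), pixel_size = 1.5, name = "zeros")
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, f)
  back <- read_mrc(f)
  expect_identical(raster_data(back), raster_data(m))
  expect_equal(attr(back, "pixel_size"), 1.5)

  p <- probability_map(matrix(0.5, 6, 5), source = "mic1")
  write_mrc(p, f)
  rp <- read_mrc(f, as = "probability_map")
  expect_s3_class(rp, "probability_map")
  expect_equal(range(rp), c(0.5, 0.5))

  lm <- label_map(matrix(rbinom(30, 1, 0.4), 5, 6))
  write_mrc(lm, f)
  expect_true(all(raster_data(read_mrc(f, as = "label_map")) %in% c(0, 1)))
})

test_that("MRC round trip is stable for 3D volumes and float32 data", {
  set.seed(4)
  v <- volume(array(runif(8^3), c(8, 8, 8)), voxel_size = 2)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(v, f)
  v1 <- read_mrc(f)
  expect_s3_class(v1, "volume")
  expect_equal(dim(v1), c(8L, 8L, 8L))
  # after one float32 quantization, further round trips are bitwise stable
  write_mrc(v1, f)
  v2 <- read_mrc(f)
  expect_identical(raster_data(v1), raster_data(v2))
  expect_equal(raster_data(v1), raster_data(v), tolerance = 1e-6)
})

test_that("malformed MRC input is rejected", {
  f <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(100), f)                       # truncated header
  expect_error(read_mrc(f), class = "micropick_error_format")
  m <- matrix(1, 4, 4); m[2, 2] <- NaN
  expect_error(write_mrc(m, f), class = "micropick_error_validation")
  expect_error(read_mrc(withr::local_tempfile()), class = "micropick_error_io")
})

test_that("raster constructors enforce their invariants", {
  expect_error(probability_map(matrix(c(0.5, 1.2), 1, 2)),
               class = "micropick_error_validation")
  expect_error(label_map(matrix(0.5, 2, 2)),
               class = "micropick_error_validation")
  expect_error(micrograph(matrix(c(1, Inf), 1, 2)),
               class = "micropick_error_validation")
  expect_error(micrograph(matrix(1, 2, 2), pixel_size = -1),
               class = "micropick_error_validation")
})

test_that("box corners convert to centers and back", {
  f <- withr::local_tempfile(fileext = ".box")
  writeLines("90\t90\t20\t20", f)
  ps <- read_coords(f, "box")
  expect_equal(ps$x, 100)
  expect_equal(ps$y, 100)
  expect_equal(ps$box_size, 20)

  # odd box: center = corner + floor(box/2)
  writeLines("10 10 21 21", f)
  expect_equal(read_coords(f, "box")$x, 20)
})

test_that("coord and star dialects parse and empty files give empty sets", {
  f <- withr::local_tempfile(fileext = ".coord")
  writeLines("10 20", f)
  ps <- read_coords(f, "coord")
  expect_equal(c(ps$x, ps$y), c(10, 20))
  writeLines(character(), f)
  expect_equal(nrow(read_coords(f, "coord")), 0)
  writeLines(c("1 2", "3 4 5"), f)
  expect_error(read_coords(f, "coord"), class = "micropick_error_format")
})

test_that("coordinate round trip is exact in all three dialects", {
  ps <- pick_set(x = c(-5, 17, 230), y = c(3, 0, 127),
                 score = c(0.9, 0.8, 0.7), box_size = 20)
  for (d in c("box", "coord", "star")) {
    f <- withr::local_tempfile(fileext = paste0(".", d))
    write_coords(ps, f, d)
    back <- read_coords(f, d, box_size = 20)
    expect_equal(back$x, ps$x, info = d)
    expect_equal(back$y, ps$y, info = d)
  }
  # empty set round trips too
  f <- withr::local_tempfile(fileext = ".star")
  write_coords(pick_set(), f, "star")
  expect_equal(nrow(read_coords(f, "star")), 0)
  expect_error(write_coords(ps, f, "weird"), class = "micropick_error_usage")
})

test_that("pick sets are score-sorted and reject duplicate centers", {
  ps <- pick_set(x = c(1, 2), y = c(1, 2), score = c(0.2, 0.9))
  expect_equal(ps$score, c(0.9, 0.2))
  expect_error(pick_set(x = c(1, 1), y = c(2, 2)),
               class = "micropick_error_validation")
})

test_that("orientation tables round trip through STAR and TSV", {
  rec <- orientation_records("mic1", cx = c(100, 200), cy = c(150, 250),
                             rot = c(10, 20), tilt = c(30, 40),
                             psi = c(50, 60), dx = c(1.5, -2), dy = c(0, 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_orientations(rec, f)
  back <- read_orientations(f, "tsv")
  expect_equal(as.data.frame(back), as.data.frame(rec))

  fs <- withr::local_tempfile(fileext = ".star")
  writeLines(c(
    "data_particles", "", "loop_",
    "_rlnCoordinateX #1", "_rlnCoordinateY #2",
    "_rlnAngleRot #3", "_rlnAngleTilt #4", "_rlnAnglePsi #5",
    "_rlnOriginX #6", "_rlnOriginY #7",
    "100 150 10 30 50 1.5 0",
    "200 250 20 40 60 -2 1"
  ), fs)
  star <- read_orientations(fs, "star", micrograph = "mic1")
  expect_equal(as.data.frame(star), as.data.frame(rec))
})
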