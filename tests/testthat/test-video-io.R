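test_that("frame directories round-trip losslessly and carry the given frame rate", {
  set.seed(10)
  frames <- lapply(1:6, function(i)
    array(sample(0:255, 8 * 10 * 3, replace = TRUE), dim = c(8, 10, 3)))
  fs <- frame_sequence(frames, frame_rate = 25)
  d <- withr::local_tempdir()
  write_video(fs, d)
  back <- read_video(d, frame_rate = 25)
  expect_equal(n_frames(back), 6)
  expect_equal(back$frame_rate, 25)
  for (i in 1:6)
    expect_equal(get_frame(back, i), frames[[i]], tolerance = 1e-12)
  # eager read gives the same frames
  eager <- read_video(d, frame_rate = 25, lazy = FALSE)
  expect_equal(get_frame(eager, 3), get_frame(back, 3))
})

test_that("video input validation rejects containers, empty dirs and missing rate", {
  d <- withr::local_tempdir()
  expect_error(read_video(file.path(d, "nope")), "no such path")
  expect_error(read_video(d), "no .png frames")
  f <- file.path(d, "clip.mp4")
  writeLines("x", f)
  expect_error(read_video(f), "not supported")
  png::writePNG(matrix(0.5, 4, 4), file.path(d, "frame_000001.png"))
  expect_error(read_video(d), "frame_rate")
})

test_that("frames are canonicalised: 0-1 rescaled, grayscale replicated, dims checked", {
  f01 <- array(0.5, dim = c(4, 4, 3))
  fs <- frame_sequence(list(f01), frame_rate = 10)
  expect_equal(get_frame(fs, 1)[1, 1, 1], 127.5)
  expect_warning(fs2 <- frame_sequence(list(matrix(10, 4, 4)), frame_rate = 1),
                 "grayscale")
  expect_equal(dim(get_frame(fs2, 1)), c(4, 4, 3))
  expect_error(frame_sequence(list(array(0, c(4, 4, 3)), array(0, c(5, 4, 3))),
                              frame_rate = 1), "dimensions")
  expect_error(frame_sequence(list(), frame_rate = 1), "non-empty")
  expect_error(frame_sequence(list(f01), frame_rate = -1), "positive")
})

test_that("bounding boxes are integer, 0-based, half-open and bounds-checked", {
  b <- bounding_box(0, 0, 3, 2)
  m <- matrix(0, 5, 5)
  m[1:2, 1:3] <- 1  # exactly the box region
  fr <- array(0, dim = c(5, 5, 3))
  # w*h pixels selected: mean of Y over an indicator region
  expect_equal(sum(primpulse:::.crop(m, b)), 6)
  expect_equal(dim(primpulse:::.crop(m, b)), c(2, 3))
  expect_error(bounding_box(0.5, 0, 2, 2), "integer")
  expect_error(bounding_box(0, 0, 0, 2), ">= 1")
  expect_error(bounding_box(-1, 0, 2, 2), "non-negative")
  fs <- frame_sequence(list(fr), frame_rate = 1)
  expect_error(roi_mean_intensity(fs, bounding_box(3, 3, 3, 3)),
               "frame 1")
})

test_that("traces round-trip through CSV to 12+ significant digits", {
  tr <- pulse_trace(c(1, 2, 3), 25)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(back$values, c(1, 2, 3))
  expect_equal(back$sample_rate, 25, tolerance = 1e-12)

  set.seed(4)
  ppg <- pulse_trace(rnorm(500), 100, t0 = 2.5)
  write_trace(ppg, f)
  b2 <- read_trace(f)
  expect_equal(b2$sample_rate, 100, tolerance = 1e-10)
  expect_equal(b2$t0, 2.5, tolerance = 1e-12)
  expect_equal(b2$values, ppg$values, tolerance = 1e-12)
})

test_that("malformed trace files fail with a line-aware parse error", {
  f <- withr::local_tempfile(fileext = ".csv")
  file.create(f)
  expect_error(read_trace(f), "line 1")
  writeLines(c("time_s,value", "0,1", "0.04,oops"), f)
  expect_error(read_trace(f), "line 3")
  writeLines(c("a,b", "0,1", "1,2"), f)
  expect_error(read_trace(f), "header")
  writeLines(c("time_s,value", "0,1", "0.5,2", "0.6,3"), f)
  expect_error(read_trace(f), "uniformly")
})
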