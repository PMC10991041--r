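test_that("peak detection counts a pure tone and rejects ripple sub-peaks", {
  s2 <- sine_trace(2, duration_s = 10, sample_rate = 25)
  pk <- detect_peaks(s2)
  expect_length(pk, 20)
  expect_true(all(diff(pk) %in% 12:13))

  expect_length(detect_peaks(pulse_trace(rep(0, 100), 25)), 0)

  t <- (0:249) / 25
  ripple <- pulse_trace(sin(2 * pi * 2 * t) + 0.15 * sin(2 * pi * 6 * t), 25)
  expect_length(detect_peaks(ripple), 20)

  expect_error(detect_peaks(pulse_trace(numeric(0), 25)), "at least one")
  expect_error(detect_peaks(s2, min_bpm = 200, max_bpm = 100), "below")
})

test_that("tied-sample plateau peaks are still detected", {
  # a symmetric pulse sampled so its apex is two equal samples
  x <- rep(0, 40)
  x[10:11] <- 1
  x[25] <- 1
  tr <- pulse_trace(x, 25)
  pk <- detect_peaks(tr, max_bpm = 250)
  expect_equal(pk, c(10L, 25L))
})

test_that("heart rate follows 60 p Fr / n exactly", {
  expect_equal(heart_rate(17, 250, 25), 102)
  expect_equal(heart_rate(0, 250, 25), 0)
  expect_equal(heart_rate(25, 600, 24), 60)
  expect_error(heart_rate(5, 0, 25), "positive")
  expect_error(heart_rate(-1, 250, 25), "negative")
})

test_that("windowed heart rate quantises to 6 BPM steps and tracks rate changes", {
  s2 <- sine_trace(2, duration_s = 100, sample_rate = 25)
  hw <- hr_windows(s2, window_s = 10)
  expect_equal(nrow(hw), 10)
  expect_true(all(abs(hw$hr_bpm - 120) <= 6))

  expect_equal(nrow(hr_windows(sine_trace(2, duration_s = 20), 10)), 2)

  # frequency step 1.7 -> 2.5 Hz at t = 50 s
  t <- (0:2499) / 25
  phase <- ifelse(t < 50, 1.7 * t, 1.7 * 50 + 2.5 * (t - 50))
  stepped <- pulse_trace(sin(2 * pi * phase), 25)
  hs <- hr_windows(stepped, 10)
  expect_true(all(abs(hs$hr_bpm[1:5] - 102) <= 6))
  expect_true(all(abs(hs$hr_bpm[6:10] - 150) <= 6))

  expect_error(hr_windows(sine_trace(2, duration_s = 5), 10), "shorter")

  # each window's value is exactly the peak-count formula on that window
  w1 <- pulse_trace(stepped$values[1:250], 25)
  expect_equal(hs$hr_bpm[1],
               heart_rate(length(detect_peaks(w1)), 250, 25))
})

test_that("the 25% interval filter reproduces literal rule application", {
  # perfectly periodic: everything kept
  pk <- seq(1, 101, by = 10)
  ints <- interpeak_intervals(pk, 25)
  expect_length(ints, 10)
  expect_true(all(ints == 0.4))

  # nine 0.5 s intervals and one 2.0 s interval at 10 Hz indexing
  pk2 <- cumsum(c(1, rep(5, 9), 20))
  i2 <- interpeak_intervals(pk2, 10)
  expect_equal(attr(i2, "raw_mean"), 0.65)
  expect_length(i2, 9)
  expect_true(all(i2 == 0.5))

  # alternating 0.2 / 1.4 s: mean 0.8, band [0.6, 1.0], nothing survives
  pk3 <- cumsum(c(1, rep(c(2, 14), 5)))
  expect_warning(i3 <- interpeak_intervals(pk3, 10), "outside")
  expect_length(i3, 0)

  expect_error(interpeak_intervals(c(1, 5), 10), "at least 3")
  expect_error(interpeak_intervals(c(1, 5, 5), 10), "increasing")
})

test_that("which interval values are kept does not depend on their order", {
  set.seed(21)
  for (rep_i in 1:5) {
    ints <- round(runif(12, 0.3, 1.0), 3)
    perm <- sample(ints)
    k1 <- interpeak_intervals(cumsum(c(1, ints * 100)), 100)
    k2 <- interpeak_intervals(cumsum(c(1, perm * 100)), 100)
    expect_equal(sort(as.numeric(k1)), sort(as.numeric(k2)))
    mu <- mean(ints)
    expect_true(all(k1 >= 0.75 * mu - 1e-9 & k1 <= 1.25 * mu + 1e-9))
  }
})

test_that("segment qualification keeps only long loss-free runs", {
  fr <- 25
  # clean 210 s video: one full-length segment
  s1 <- qualify_segments(rep(FALSE, 210 * fr), fr)
  expect_equal(nrow(s1), 1)
  expect_equal(c(s1$start_frame, s1$end_frame), c(1, 210 * fr))

  # single loss at t = 50 s splits a 120 s video into two sub-100 s runs
  f2 <- rep(FALSE, 120 * fr)
  f2[50 * fr] <- TRUE
  expect_equal(nrow(qualify_segments(f2, fr)), 0)

  # losses at 10 s and 115 s of a 120 s video leave one 105 s middle run
  f3 <- rep(FALSE, 120 * fr)
  f3[10 * fr] <- TRUE
  f3[115 * fr] <- TRUE
  s3 <- qualify_segments(f3, fr)
  expect_equal(nrow(s3), 1)
  expect_equal(s3$start_frame, 10 * fr + 1)
  expect_equal(s3$end_frame, 115 * fr - 1)

  expect_equal(nrow(qualify_segments(logical(0), fr)), 0)
  # shorter qualifying length admits shorter runs
  expect_equal(nrow(qualify_segments(f2, fr, min_len_s = 30)), 2)
})
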