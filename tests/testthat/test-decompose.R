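test_that("band specifications validate their edges", {
  expect_equal(cardiac_band()$low_hz, 1.5)
  expect_equal(cardiac_band()$high_hz, 4.2)
  expect_equal(respiratory_band()$low_hz, 0.25)
  expect_equal(respiratory_band()$high_hz, 0.8)
  expect_equal(cardiac_band()$order, 3L)
  expect_error(band_spec(2, 1), "low < high")
  expect_error(band_spec(-1, 2), "low < high")
})

test_that("the cardiac band-pass passes 2 Hz, rejects 0.3 Hz, and is near-idempotent", {
  z <- pulse_trace(rep(0, 300), 25)
  expect_equal(bandpass(z)$values, rep(0, 300))

  s2 <- sine_trace(2, duration_s = 40)
  out <- bandpass(s2)$values
  core <- out[200:800]  # away from filter edge transients
  expect_lt(abs(max(abs(core)) - 1), 0.02)

  s03 <- sine_trace(0.3, duration_s = 40)
  expect_lt(max(abs(bandpass(s03)$values[200:800])), 0.05)

  twice <- bandpass(bandpass(s2))$values[200:800]
  expect_lt(abs(max(abs(twice)) / max(abs(core)) - 1), 0.04)

  expect_error(bandpass(sine_trace(2, sample_rate = 8)), "Nyquist")
  expect_error(bandpass(pulse_trace(1:5, 25)), "too short")
})

test_that("EMD separates well-spaced tones and reconstructs completely", {
  ramp <- pulse_trace(seq(0, 1, length.out = 100), 25)
  d0 <- emd(ramp)
  expect_length(d0$imfs, 0)
  expect_equal(d0$residual$values, ramp$values)

  t <- (0:999) / 25
  x <- sin(2 * pi * 3 * t) + sin(2 * pi * 0.3 * t)
  d <- emd(pulse_trace(x, 25))
  expect_gte(length(d$imfs), 2)
  f1 <- dominant_frequency(d$imfs[[1]])
  f2 <- dominant_frequency(d$imfs[[2]])
  expect_lt(abs(f1 - 3) / 3, 0.1)
  expect_lt(abs(f2 - 0.3) / 0.3, 0.1)
  expect_lt(reconstruction_error(d, x), 1e-8)
})

test_that("CEEMDAN is complete, recovers a noisy tone, and is ensemble-stable", {
  set.seed(14)
  t <- (0:749) / 25
  s <- sin(2 * pi * 1.7 * t)
  x <- s + rnorm(750, 0, sd(s))  # SNR 0 dB
  tr <- pulse_trace(x, 25)
  d <- ceemdan(tr, ensemble_size = 50, seed = 3)
  expect_lt(reconstruction_error(d, x), 1e-8)
  fr <- vapply(d$imfs, function(im)
    tryCatch(dominant_frequency(im), error = function(e) NA_real_), 0)
  expect_true(any(abs(fr - 1.7) / 1.7 < 0.1, na.rm = TRUE))

  d2 <- ceemdan(tr, ensemble_size = 50, seed = 4)
  expect_gt(cor(d$imfs[[1]]$values, d2$imfs[[1]]$values), 0.95)

  expect_error(ceemdan(tr, ensemble_size = 1), "at least 2")
  expect_error(ceemdan(pulse_trace(1:4, 25)), "too short")
})

test_that("decomposition matches the independent reference implementation", {
  set.seed(31)
  t <- (0:399) / 25
  x <- sin(2 * pi * 2.2 * t) + 0.6 * sin(2 * pi * 0.5 * t) +
    rnorm(400, 0, 0.3)
  a <- emd(pulse_trace(x, 25))
  b <- ref_emd(x)
  k <- min(length(a$imfs), length(b$imfs))
  expect_gte(k, 2)
  for (j in seq_len(k))
    expect_gt(cor(a$imfs[[j]]$values, b$imfs[[j]]), 0.99)

  ca <- ceemdan(pulse_trace(x, 25), ensemble_size = 20, seed = 7,
                max_imfs = 6)
  cb <- ref_ceemdan(x, ensemble_size = 20, seed = 7, max_imfs = 6)
  k2 <- min(length(ca$imfs), length(cb$imfs))
  expect_gte(k2, 2)
  for (j in seq_len(k2))
    expect_gt(cor(ca$imfs[[j]]$values, cb$imfs[[j]]), 0.99)
})

test_that("dominant frequency locates synthetic tones to 0.05 Hz", {
  expect_lt(abs(dominant_frequency(sine_trace(1.7)) - 1.7), 0.05)
  expect_lt(abs(dominant_frequency(sine_trace(1.8)) - 1.8), 0.05)
  expect_error(dominant_frequency(pulse_trace(rep(3, 100), 25)), "constant")
  expect_error(dominant_frequency(pulse_trace(1:8, 25)), "too short")
})

test_that("frequency converts to beats per minute as 60 f", {
  expect_identical(hz_to_bpm(1.7), 102)
  expect_identical(hz_to_bpm(1.8), 108)
  expect_identical(hz_to_bpm(0), 0)
  expect_error(hz_to_bpm(-0.1), "non-negative")
})

test_that("cardiac IMF selection is band-constrained", {
  d <- ceemdan(bandpass(sine_trace(2, duration_s = 30)), ensemble_size = 20,
               seed = 5)
  sel <- select_cardiac_imf(d)
  expect_equal(sel$index, 1L)
  expect_lt(abs(dominant_frequency(sel$trace) - 2), 0.1)

  # constructed counter-case: IMF 1 is 6 Hz noise, IMF 2 the 2 Hz pulse
  hi <- sine_trace(6, duration_s = 20, sample_rate = 25)
  lo <- sine_trace(2, duration_s = 20, sample_rate = 25)
  fake <- fake_imf_set(list(hi, lo), pulse_trace(rep(0, 500), 25))
  expect_equal(select_cardiac_imf(fake)$index, 2L)

  slow <- fake_imf_set(list(sine_trace(0.5, 20), sine_trace(0.2, 20)),
                       pulse_trace(rep(0, 500), 25))
  expect_error(select_cardiac_imf(slow), "no cardiac")
})

test_that("the band-passed CEEMDAN chain recovers synthetic cardiac frequencies within 3 BPM", {
  set.seed(77)
  for (f in c(1.6, 2.0, 2.5, 3.0)) {
    t <- (0:1499) / 25
    s <- sin(2 * pi * f * t)
    x <- s + rnorm(1500, 0, sd(s) * 10^(-5 / 20))  # SNR 5 dB
    sel <- select_cardiac_imf(ceemdan(bandpass(pulse_trace(x, 25)),
                                      ensemble_size = 30, seed = 1))
    bpm <- hz_to_bpm(dominant_frequency(sel$trace))
    expect_lt(abs(bpm - 60 * f), 3)
  }
})
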