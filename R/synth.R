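#' Synthetic video specification
#'
#' Describes a synthetic test video with known cardiac and respiratory
#' ground truth. A textured "face" patch sits on a plain background; its
#' intensity is modulated by a cardiac sinusoid (`pulse_amplitude` units on
#' the 0--255 luma scale), a respiratory sinusoid, a slow global
#' illumination drift and white frame-to-frame illumination noise -- the
#' quantity the ROI mean-intensity measurement actually sees. The patch can
#' translate along a per-frame motion path to exercise the tracker. Frames
#' are quantised to 8-bit integers, as a camera would deliver.
#'
#' @param hr_bpm heart rate in beats per minute: a scalar, or a step
#'   schedule as a data frame with columns `time_s` (starting at 0) and
#'   `hr_bpm`.
#' @param rr_bpm respiratory rate in breaths per minute.
#' @param pulse_amplitude cardiac modulation amplitude in luma units on the
#'   0--255 scale (default 1: subtle motion).
#' @param resp_amplitude respiratory modulation amplitude (same units).
#' @param noise_std standard deviation of the white per-frame illumination
#'   noise (luma units).
#' @param illum_drift `c(amplitude, frequency_hz)` of the slow sinusoidal
#'   global illumination change.
#' @param motion_path `NULL` (static) or an `n_frames x 2` matrix of
#'   per-frame `(dx, dy)` pixel offsets of the face patch.
#' @param hrv_sd beat-to-beat variability: each interbeat interval is
#'   perturbed by `N(0, hrv_sd)` seconds, and the perturbed beat sequence
#'   drives both the video's cardiac phase and the reference PPG. Default 0
#'   (strictly periodic pulse). Without it the video's interbeat intervals
#'   collapse onto the frame grid and interval-distribution comparisons are
#'   degenerate.
#' @param duration_s video duration in seconds.
#' @param frame_rate frames per second (default 25).
#' @param frame_size frame dimensions `c(height, width)` (default 120 x 160).
#' @param jitter_sd beat-time jitter for the reference PPG, in seconds.
#' @param dropouts list of `c(start_s, end_s)` spans where the reference
#'   PPG signal is blanked (sensor dropout bursts).
#' @param seed RNG seed; every random element (texture, noise, jitter)
#'   derives from it.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(hr_bpm = 120, rr_bpm = 15, pulse_amplitude = 1.0,
                       resp_amplitude = 1.0, noise_std = 0.5,
                       illum_drift = c(2, 0.05), motion_path = NULL,
                       duration_s = 110, frame_rate = 25,
                       frame_size = c(120, 160), hrv_sd = 0, jitter_sd = 0,
                       dropouts = NULL, seed = 1) {
  if (is.numeric(hr_bpm) && length(hr_bpm) == 1) {
    if (frame_rate <= 2 * hr_bpm / 60)
      .stopf("frame_rate %.3g below Nyquist for %.3g BPM", frame_rate, hr_bpm)
  } else if (!is.data.frame(hr_bpm) ||
             !all(c("time_s", "hr_bpm") %in% names(hr_bpm))) {
    .stopf("hr_bpm must be a scalar or a data.frame(time_s, hr_bpm)")
  }
  structure(list(hr_bpm = hr_bpm, rr_bpm = rr_bpm,
                 pulse_amplitude = pulse_amplitude,
                 resp_amplitude = resp_amplitude, noise_std = noise_std,
                 illum_drift = illum_drift, motion_path = motion_path,
                 duration_s = duration_s, frame_rate = frame_rate,
                 frame_size = as.integer(frame_size), hrv_sd = hrv_sd,
                 jitter_sd = jitter_sd, dropouts = dropouts, seed = seed),
            class = "synth_spec")
}

# Cardiac phase phi(t) in cycles and instantaneous frequency, supporting a
# stepwise HR schedule.
.phase_fn <- function(spec) {
  if (is.data.frame(spec$hr_bpm)) {
    tb <- spec$hr_bpm$time_s
    fb <- spec$hr_bpm$hr_bpm / 60
    if (tb[1] != 0) .stopf("hr schedule must start at time_s = 0")
    cum <- c(0, cumsum(fb[-length(fb)] * diff(tb)))
    f_at <- function(t) fb[pmax(findInterval(t, tb), 1)]
    phi <- function(t) {
      j <- pmax(findInterval(t, tb), 1)
      cum[j] + fb[j] * (t - tb[j])
    }
  } else {
    f0 <- spec$hr_bpm / 60
    f_at <- function(t) rep(f0, length(t))
    phi <- function(t) f0 * t
  }
  list(f_at = f_at, phi = phi)
}

# True beat times: solutions of phi(t) = k + 1/4 (maxima of sin(2 pi phi)).
.beat_times <- function(spec) {
  ph <- .phase_fn(spec)
  tt <- seq(0, spec$duration_s, by = 1 / (20 * spec$frame_rate))
  p <- ph$phi(tt)
  ks <- seq(ceiling(p[1] - 0.25), floor(p[length(p)] - 0.25)) + 0.25
  vapply(ks, function(k) {
    i <- which(p >= k)[1]
    if (i <= 1) return(tt[1])
    # linear interpolation within the bracketing step
    tt[i - 1] + (k - p[i - 1]) / (p[i] - p[i - 1]) * (tt[i] - tt[i - 1])
  }, numeric(1))
}

# True beat times including beat-to-beat variability (shared between the
# video and the reference PPG; deterministic given the spec's seed).
.true_beats <- function(spec) {
  base <- .beat_times(spec)
  if (spec$hrv_sd <= 0 || length(base) < 2) return(base)
  set.seed(spec$seed + 2)
  d <- diff(base)
  d <- pmax(d + rnorm(length(d), 0, spec$hrv_sd), 0.5 * d)
  out <- base[1] + c(0, cumsum(d))
  out[out <= spec$duration_s]   # the recording ends at duration_s
}

# Cardiac phase (in cycles) passing through 0.25 + k at beat k: piecewise
# linear between beats, linearly extrapolated at the ends.
.beat_phase_fn <- function(beats) {
  p <- 0.25 + seq_along(beats) - 1
  function(t) {
    j <- findInterval(t, beats)
    j <- pmin(pmax(j, 1), length(beats) - 1)
    slope <- (p[j + 1] - p[j]) / (beats[j + 1] - beats[j])
    p[j] + slope * (t - beats[j])
  }
}

#' Generate a synthetic test video
#'
#' Renders the video described by a [synth_spec()] and returns it together
#' with its ground truth. With `lazy = TRUE` (default) frames are rendered
#' on demand from precomputed random draws, so arbitrarily long videos cost
#' no memory; the same spec always yields bit-identical frames.
#'
#' @param spec a [synth_spec()].
#' @param lazy render frames on demand (default) or materialise them all.
#' @return List with `frames` (a [frame_sequence()]) and `truth`: true beat
#'   times (s), mean heart rate, a per-window true-HR table (10 s windows)
#'   and the face-patch base position.
#' @export
make_video <- function(spec, lazy = TRUE) {
  stopifnot(inherits(spec, "synth_spec"))
  h <- spec$frame_size[1]; w <- spec$frame_size[2]
  n <- round(spec$duration_s * spec$frame_rate)
  beats <- .true_beats(spec)
  phi <- if (spec$hrv_sd > 0 && length(beats) >= 2) .beat_phase_fn(beats)
         else .phase_fn(spec)$phi

  set.seed(spec$seed)
  fh <- max(8L, as.integer(round(h * 0.4)))
  fw <- max(8L, as.integer(round(w * 0.4)))
  tex <- .smooth_texture(fh, fw, mean = 120, contrast = 30)
  frame_noise <- rnorm(n, 0, spec$noise_std)

  base_y <- as.integer(floor((h - fh) / 2))
  base_x <- as.integer(floor((w - fw) / 2))
  if (is.null(spec$motion_path)) {
    path <- matrix(0L, n, 2)
  } else {
    path <- spec$motion_path
    if (nrow(path) != n) .stopf("motion_path needs one (dx, dy) row per frame (%d)", n)
    path <- round(path)
  }
  ox <- base_x + path[, 1]; oy <- base_y + path[, 2]
  if (any(ox < 0) || any(oy < 0) || any(ox + fw > w) || any(oy + fh > h))
    .stopf("motion path moves the face patch outside the %dx%d frame", h, w)

  # additive modulation is specified in luma units; convert to pixel units
  # so that the Y-channel amplitude equals pulse_amplitude exactly
  luma_gain <- sum(color_matrix("paper")$matrix[1, ]) / 255
  tvec <- (seq_len(n) - 1) / spec$frame_rate
  mod <- (spec$pulse_amplitude * sin(2 * pi * phi(tvec)) +
          spec$resp_amplitude * sin(2 * pi * (spec$rr_bpm / 60) * tvec) +
          spec$illum_drift[1] * sin(2 * pi * spec$illum_drift[2] * tvec) +
          frame_noise) / luma_gain

  render <- function(i) {
    m <- matrix(60, h, w)
    m[(oy[i] + 1):(oy[i] + fh), (ox[i] + 1):(ox[i] + fw)] <- tex + mod[i]
    m <- round(pmin(pmax(m, 0), 255))
    array(rep(m, 3), dim = c(h, w, 3))
  }

  fs <- if (lazy) {
    frame_sequence(frame_fn = render, n_frames = n, dim = c(h, w),
                   frame_rate = spec$frame_rate)
  } else {
    frame_sequence(lapply(seq_len(n), render), frame_rate = spec$frame_rate)
  }

  wstarts <- if (spec$duration_s >= 10)
    seq(0, spec$duration_s - 10, by = 10) else numeric(0)
  truth_hr <- data.frame(window_start_s = wstarts,
                         hr_bpm = 60 * (phi(wstarts + 10) - phi(wstarts)) / 10)
  truth <- list(beat_times = beats,
                mean_hr_bpm = 60 * (phi(spec$duration_s) - phi(0)) /
                  spec$duration_s,
                window_hr = truth_hr,
                face_box = bounding_box(base_x, base_y, fw, fh),
                face_offsets = cbind(dx = ox - base_x, dy = oy - base_y))
  list(frames = fs, truth = truth)
}

# Smooth pseudo-random texture: white noise blurred with a separable
# moving-average kernel, standardised, then scaled.
.smooth_texture <- function(h, w, mean = 120, contrast = 30, passes = 3,
                            k = 5) {
  m <- matrix(runif(h * w), h, w)
  for (p in seq_len(passes)) {
    m <- t(apply(m, 1, function(r) stats::filter(r, rep(1 / k, k),
                                                 circular = TRUE)))
    m <- apply(m, 2, function(cc) stats::filter(cc, rep(1 / k, k),
                                                circular = TRUE))
  }
  m <- (m - base::mean(m)) / sd(m)
  mean + contrast * m
}

#' Generate a synthetic reference pulse waveform
#'
#' A quasi-periodic pulse train standing in for a contact PPG recording:
#' Gaussian-shaped pulses at the spec's true beat times, with optional
#' beat-time jitter (`jitter_sd`) and dropout bursts (`dropouts`) emulating
#' noisy sensor segments whose spurious intervals the 25% plausibility
#' filter must remove.
#'
#' @param spec a [synth_spec()].
#' @param sample_rate output sampling rate in Hz (default 100).
#' @return A [pulse_trace()].
#' @export
make_ppg <- function(spec, sample_rate = 100) {
  stopifnot(inherits(spec, "synth_spec"))
  beats <- .true_beats(spec)
  set.seed(spec$seed + 1)
  if (spec$jitter_sd > 0)
    beats <- sort(beats + rnorm(length(beats), 0, spec$jitter_sd))
  tt <- seq(0, spec$duration_s, by = 1 / sample_rate)
  tau <- 0.08 * mean(diff(beats))
  x <- numeric(length(tt))
  for (b in beats) {
    lo <- max(1, floor((b - 4 * tau) * sample_rate) + 1)
    hi <- min(length(tt), ceiling((b + 4 * tau) * sample_rate) + 1)
    if (lo > hi) next
    x[lo:hi] <- x[lo:hi] + exp(-(tt[lo:hi] - b)^2 / (2 * tau^2))
  }
  for (d in spec$dropouts) {
    x[tt >= d[1] & tt <= d[2]] <- 0
  }
  pulse_trace(x, sample_rate)
}
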