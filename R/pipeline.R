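#' Estimate the cardiac signal from video
#'
#' The full motion-based pipeline: read or accept a frame sequence, track
#' the facial ROI with a MOSSE correlation filter (optional), extract the
#' ROI mean-luma trace, band-pass it to the cardiac band (third-order
#' Butterworth, zero phase), decompose with CEEMDAN, select the cardiac IMF,
#' detect pulse peaks, and convert them to windowed heart rate and
#' interbeat intervals. Analysis is restricted to qualifying segments:
#' maximal runs without target loss of at least `min_segment_s` seconds.
#'
#' @param video a [frame_sequence()] or a path accepted by [read_video()].
#' @param roi initial ROI: a [bounding_box()] or `c(x, y, width, height)`.
#' @param track stabilise the ROI with the MOSSE tracker (default `TRUE`);
#'   with `FALSE` the initial box is used for every frame.
#' @param eta tracker learning rate (default 0.125).
#' @param psr_threshold peak-to-sidelobe ratio below which the target is
#'   declared lost (default 5).
#' @param band cardiac [band_spec()] (default 1.5--4.2 Hz, order 3).
#' @param noise_std,ensemble_size,max_imfs CEEMDAN parameters (defaults
#'   0.2, 100, 9).
#' @param window_s heart-rate averaging window in seconds (default 10).
#' @param filter_frac interbeat-interval plausibility half-width (default
#'   0.25).
#' @param min_segment_s minimum qualifying segment duration in seconds
#'   (default 100).
#' @param min_bpm,max_bpm plausible heart-rate range (defaults 90, 250).
#' @param cm [color_matrix()] for the luma conversion.
#' @param frame_rate frame rate, required when `video` is a frame
#'   directory.
#' @param seed seed for the CEEMDAN noise ensemble (default 1).
#' @return An object of class `pulse_estimate` with components
#'   `hr_bpm` (session heart rate: `60 p F_r / n` over all analysed
#'   segment frames), `hr_series` (data frame `window_start_s`, `hr_bpm`),
#'   `intervals`
#'   (seconds, 25%-filtered), `peak_times` (s), `segments`, `boxes`
#'   (per-frame tracking table), `trace_raw`, `trace_cardiac` (selected IMF
#'   per segment), `imf_index`, `status` (`"ok"` or `"no_segment"`) and the
#'   configuration. Methods: `print`, `summary`, `plot`, `as.data.frame`,
#'   `coef`.
#' @examples
#' \donttest{
#' sv <- make_video(synth_spec(hr_bpm = 120, duration_s = 30, seed = 7))
#' est <- estimate_pulse(sv$frames, sv$truth$face_box, track = FALSE,
#'                       min_segment_s = 30, ensemble_size = 30)
#' coef(est)
#' }
#' @export
estimate_pulse <- function(video, roi, track = TRUE, eta = 0.125,
                           psr_threshold = 5, band = cardiac_band(),
                           noise_std = 0.2, ensemble_size = 100,
                           max_imfs = 9, window_s = 10, filter_frac = 0.25,
                           min_segment_s = 100, min_bpm = 90, max_bpm = 250,
                           cm = color_matrix(), frame_rate = NULL,
                           seed = 1) {
  cl <- match.call()
  if (is.character(video)) video <- read_video(video, frame_rate = frame_rate)
  stopifnot(inherits(video, "frame_sequence"))
  fr <- video$frame_rate

  te <- .track_extract(video, roi, track = track, eta = eta,
                       psr_threshold = psr_threshold, cm = cm, seed = seed)
  segs <- qualify_segments(te$boxes$lost, fr, min_segment_s)

  config <- list(track = track, eta = eta, psr_threshold = psr_threshold,
                 band = unclass(band), noise_std = noise_std,
                 ensemble_size = ensemble_size, max_imfs = max_imfs,
                 window_s = window_s, filter_frac = filter_frac,
                 min_segment_s = min_segment_s, min_bpm = min_bpm,
                 max_bpm = max_bpm, color_matrix = cm$preset, seed = seed,
                 frame_rate = fr, roi = unclass(.as_box(roi)))

  out <- list(hr_bpm = NA_real_,
              hr_series = data.frame(window_start_s = numeric(0),
                                     hr_bpm = numeric(0)),
              intervals = numeric(0), peak_times = numeric(0),
              segments = segs, boxes = te$boxes, trace_raw = te$trace,
              trace_cardiac = list(), imf_index = integer(0),
              status = if (nrow(segs) == 0) "no_segment" else "ok",
              config = config, call = cl)
  class(out) <- "pulse_estimate"
  if (nrow(segs) == 0) return(out)

  total_p <- 0; total_n <- 0

  for (s in seq_len(nrow(segs))) {
    i0 <- segs$start_frame[s]; i1 <- segs$end_frame[s]
    seg_tr <- pulse_trace(te$trace$values[i0:i1], fr, t0 = (i0 - 1) / fr)
    filt <- bandpass(seg_tr, band)
    dec <- ceemdan(filt, noise_std = noise_std,
                   ensemble_size = ensemble_size, seed = seed + s,
                   max_imfs = max_imfs)
    sel <- tryCatch(select_cardiac_imf(dec, band), error = function(e) NULL)
    if (is.null(sel)) next
    cardiac <- sel$trace
    pk <- detect_peaks(cardiac, min_bpm, max_bpm)
    hr <- hr_windows(cardiac, window_s, min_bpm, max_bpm)
    ints <- if (length(pk) >= 3)
      interpeak_intervals(pk, fr, filter_frac) else numeric(0)
    out$hr_series <- rbind(out$hr_series, hr)
    out$intervals <- c(out$intervals, as.numeric(ints))
    out$peak_times <- c(out$peak_times, cardiac$t0 + (pk - 1) / fr)
    out$trace_cardiac[[s]] <- cardiac
    out$imf_index <- c(out$imf_index, sel$index)
    total_p <- total_p + length(pk)
    total_n <- total_n + (i1 - i0 + 1)
  }
  if (nrow(out$hr_series) == 0) {
    out$status <- "no_segment"
  } else {
    # session heart rate: peak count over all analysed segment frames
    out$hr_bpm <- heart_rate(total_p, total_n, fr)
  }
  out
}

#' @export
print.pulse_estimate <- function(x, ...) {
  cat("Motion-based pulse estimate\n")
  cat(sprintf("  frames: %d @ %.6g fps, tracking %s\n",
              nrow(x$boxes), x$config$frame_rate,
              if (x$config$track) "on" else "off"))
  cat(sprintf("  qualifying segments (>= %.4g s): %d\n",
              x$config$min_segment_s, nrow(x$segments)))
  if (x$status == "no_segment") {
    cat("  no qualifying noise-free segment: no heart rate estimated\n")
  } else {
    cat(sprintf("  heart rate: %.1f BPM (peak count over segments; %d windows of %.4g s)\n",
                x$hr_bpm, nrow(x$hr_series), x$config$window_s))
    cat(sprintf("  interbeat intervals kept: %d (mean %.3f s)\n",
                length(x$intervals), mean(x$intervals)))
  }
  invisible(x)
}

#' @export
summary.pulse_estimate <- function(object, ...) {
  hr <- object$hr_series$hr_bpm
  s <- list(status = object$status,
            hr_bpm = object$hr_bpm,
            n_frames = nrow(object$boxes),
            n_segments = nrow(object$segments),
            n_windows = nrow(object$hr_series),
            hr_mean = mean(hr, na.rm = TRUE),
            hr_sd = sd(hr[!is.na(hr)]),
            hr_range = if (length(hr)) range(hr, na.rm = TRUE) else c(NA, NA),
            n_intervals = length(object$intervals),
            ibi_mean = mean(object$intervals),
            ibi_sd = sd(object$intervals),
            imf_index = object$imf_index,
            frames_lost = sum(object$boxes$lost))
  class(s) <- "summary.pulse_estimate"
  s
}

#' @export
print.summary.pulse_estimate <- function(x, ...) {
  cat("Motion-based pulse estimate -- summary\n")
  cat(sprintf("  status          : %s\n", x$status))
  cat(sprintf("  frames / lost   : %d / %d\n", x$n_frames, x$frames_lost))
  cat(sprintf("  segments        : %d\n", x$n_segments))
  if (x$n_windows > 0) {
    cat(sprintf("  session HR      : %.1f BPM\n", x$hr_bpm))
    cat(sprintf("  HR windows      : %d\n", x$n_windows))
    cat(sprintf("  HR mean (sd)    : %.1f (%.1f) BPM\n", x$hr_mean, x$hr_sd))
    cat(sprintf("  HR range        : %.1f-%.1f BPM\n",
                x$hr_range[1], x$hr_range[2]))
    cat(sprintf("  intervals kept  : %d, mean %.3f s (sd %.3f)\n",
                x$n_intervals, x$ibi_mean, x$ibi_sd))
    cat(sprintf("  cardiac IMF     : %s\n",
                paste(x$imf_index, collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.pulse_estimate <- function(object, ...) {
  c(hr_bpm = object$hr_bpm, ibi_s = mean(object$intervals))
}

#' @export
as.data.frame.pulse_estimate <- function(x, ...) x$hr_series

#' @export
plot.pulse_estimate <- function(x, ...) {
  op <- par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(trace_times(x$trace_raw), x$trace_raw$values, type = "l",
       xlab = "time (s)", ylab = "ROI mean Y", main = "raw intensity trace")
  if (length(x$trace_cardiac) > 0) {
    tc <- x$trace_cardiac[[1]]
    plot(trace_times(tc), tc$values, type = "l", xlab = "time (s)",
         ylab = "cardiac IMF", main = "cardiac component")
    pt <- x$peak_times[x$peak_times >= tc$t0 &
                       x$peak_times <= tc$t0 + length(tc) / tc$sample_rate]
    points(pt, tc$values[round((pt - tc$t0) * tc$sample_rate) + 1],
           col = 2, pch = 19, cex = 0.6)
  } else {
    plot.new()
  }
  if (nrow(x$hr_series) > 0) {
    plot(x$hr_series$window_start_s, x$hr_series$hr_bpm, type = "b",
         xlab = "window start (s)", ylab = "HR (BPM)",
         main = sprintf("windowed heart rate (%g s windows)",
                        x$config$window_s))
  } else {
    plot.new()
  }
  invisible(x)
}

#' Run the pipeline and write its results
#'
#' Convenience wrapper around [estimate_pulse()] that writes the heart-rate
#' series, kept interbeat intervals and per-frame tracking table as CSV,
#' plus a JSON run manifest (configuration, seed, package version) that
#' fully determines the outputs: replaying a manifest reproduces them.
#'
#' @inheritParams estimate_pulse
#' @param out_dir output directory (created if needed).
#' @param ... further arguments to [estimate_pulse()].
#' @return The `pulse_estimate`, invisibly.
#' @export
run_pipeline <- function(video, roi, out_dir, ...) {
  est <- estimate_pulse(video, roi, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(est$hr_series, file.path(out_dir, "hr_windows.csv"),
            row.names = FALSE)
  write.csv(data.frame(interval_s = est$intervals),
            file.path(out_dir, "intervals.csv"), row.names = FALSE)
  write.csv(est$boxes, file.path(out_dir, "boxes.csv"), row.names = FALSE)
  manifest <- list(package = "primpulse",
                   version = as.character(utils::packageVersion("primpulse")),
                   status = est$status, config = est$config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(est)
}
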