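#' Detect pulse peaks
#'
#' Local maxima of the cardiac trace, kept if their topographic prominence
#' is at least `prominence_frac` times the trace standard deviation and if
#' they are separated by at least `60 / max_bpm` seconds (no physiologically
#' impossible double beats). When two candidate peaks are closer than the
#' minimum separation the higher one wins.
#'
#' @param trace a [pulse_trace()] (the selected cardiac IMF).
#' @param min_bpm,max_bpm plausible heart-rate range in beats per minute
#'   (defaults 90 and 250, the cardiac band).
#' @param prominence_frac prominence threshold as a fraction of the trace
#'   standard deviation (default 0.1). The minimum-separation rule is the
#'   primary guard against spurious sub-peaks; the prominence cut only
#'   rejects numerical ripple, so that genuine beats in amplitude-dipped
#'   stretches of a decomposed component are not discarded.
#' @return Integer vector of strictly increasing peak sample indices
#'   (1-based).
#' @export
detect_peaks <- function(trace, min_bpm = 90, max_bpm = 250,
                         prominence_frac = 0.1) {
  stopifnot(inherits(trace, "pulse_trace"))
  if (min_bpm >= max_bpm) .stopf("min_bpm must be below max_bpm")
  x <- trace$values
  n <- length(x)
  if (n == 0) .stopf("empty trace")
  if (n < 3) return(integer(0))
  cand <- .local_maxima(x)
  if (length(cand) == 0) return(integer(0))
  prom <- .prominence(x, cand)
  thr <- prominence_frac * sd(x)
  cand <- cand[prom >= thr]
  if (length(cand) == 0) return(integer(0))
  min_sep <- trace$sample_rate * 60 / max_bpm
  sort(.enforce_separation(cand, x[cand], min_sep))
}

# Interior local maxima; a plateau (run of tied samples) higher than both
# neighbouring runs contributes its midpoint. Sampled symmetric peaks often
# land as two tied samples, which a strict comparison would miss.
.local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  j <- 2:(k - 1)
  top <- j[r$values[j] > r$values[j - 1] & r$values[j] > r$values[j + 1]]
  as.integer((starts[top] + ends[top]) %/% 2)
}

# Topographic prominence of peaks at indices `peaks` in series x: height
# above the higher of the two key saddles (minima between the peak and the
# nearest higher ground on each side; series ends count as boundaries).
.prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    hp <- x[p]
    left <- x[seq_len(p - 1)]
    higher <- which(left > hp)
    lmin <- min(x[(if (length(higher)) max(higher) else 1):p])
    right <- x[p:length(x)]
    higher <- which(right > hp)
    rmin <- min(right[1:(if (length(higher)) min(higher) else length(right))])
    hp - max(lmin, rmin)
  }, numeric(1))
}

# Greedy minimum-separation filter: higher peaks claim their neighbourhood.
.enforce_separation <- function(idx, height, min_sep) {
  ord <- order(height, decreasing = TRUE)
  keep <- logical(length(idx))
  for (j in ord) {
    if (any(keep & abs(idx - idx[j]) < min_sep)) next
    keep[j] <- TRUE
  }
  idx[keep]
}

#' Heart rate from a peak count
#'
#' `HR = 60 * p * F_r / n` beats per minute, where `p` is the number of
#' detected peaks, `n` the number of frames in the segment and `F_r` the
#' frame rate.
#'
#' @param p_peaks number of peaks (non-negative).
#' @param n_frames number of frames in the segment (positive).
#' @param frame_rate frames per second (positive).
#' @return Heart rate in beats per minute.
#' @examples
#' heart_rate(17, 250, 25)  # 102 BPM
#' @export
heart_rate <- function(p_peaks, n_frames, frame_rate) {
  if (n_frames <= 0 || frame_rate <= 0)
    .stopf("n_frames and frame_rate must be positive")
  if (p_peaks < 0) .stopf("peak count cannot be negative")
  60 * p_peaks * frame_rate / n_frames
}

#' Windowed heart-rate series
#'
#' Splits the trace into consecutive non-overlapping windows of `window_s`
#' seconds and computes each window's heart rate by peak counting
#' ([detect_peaks()] on the window, then [heart_rate()]). A window with no
#' detected peaks yields `NA`, not 0. At a 10 s window the count
#' quantisation step is 6 beats per minute.
#'
#' @param trace a [pulse_trace()] at least one window long.
#' @param window_s window length in seconds (default 10).
#' @inheritParams detect_peaks
#' @return Data frame with columns `window_start_s` and `hr_bpm`.
#' @export
hr_windows <- function(trace, window_s = 10, min_bpm = 90, max_bpm = 250,
                       prominence_frac = 0.1) {
  stopifnot(inherits(trace, "pulse_trace"))
  sr <- trace$sample_rate
  wn <- floor(window_s * sr)
  n <- length(trace$values)
  if (n < wn) .stopf("trace (%.3g s) shorter than one %.3g s window",
                     n / sr, window_s)
  k <- floor(n / wn)
  starts <- (seq_len(k) - 1) * wn
  hr <- vapply(starts, function(s) {
    w <- pulse_trace(trace$values[(s + 1):(s + wn)], sr)
    p <- length(detect_peaks(w, min_bpm, max_bpm, prominence_frac))
    if (p == 0) NA_real_ else heart_rate(p, wn, sr)
  }, numeric(1))
  data.frame(window_start_s = trace$t0 + starts / sr, hr_bpm = hr)
}

#' Interbeat intervals with the 25% plausibility filter
#'
#' Raw intervals are successive peak-index differences divided by the frame
#' rate. Only intervals whose length is within `filter_frac` (default 25%)
#' of the mean raw interval are kept; the mean is computed once on the raw
#' intervals, not iterated. Intervals distorted by missed or spurious peaks
#' fall outside the band and are discarded.
#'
#' @param peak_indices strictly increasing peak sample indices (at least 3
#'   peaks).
#' @param frame_rate sampling rate of the peak indices in Hz.
#' @param filter_frac half-width of the plausibility band around the mean
#'   raw interval (default 0.25).
#' @return Numeric vector of kept intervals in seconds, with attributes
#'   `raw` (all intervals) and `raw_mean`.
#' @export
interpeak_intervals <- function(peak_indices, frame_rate, filter_frac = 0.25) {
  if (length(peak_indices) < 3)
    .stopf("need at least 3 peaks to form intervals")
  if (any(diff(peak_indices) <= 0))
    .stopf("peak indices must be strictly increasing")
  raw <- diff(peak_indices) / frame_rate
  mu <- mean(raw)
  keep <- raw >= (1 - filter_frac) * mu & raw <= (1 + filter_frac) * mu
  if (!any(keep))
    .warnf("all %d intervals fall outside %.0f%% of the mean (%.3g s)",
           length(raw), 100 * filter_frac, mu)
  out <- raw[keep]
  attr(out, "raw") <- raw
  attr(out, "raw_mean") <- mu
  out
}

#' Qualify noise-free segments
#'
#' A segment qualifies for analysis when it is a maximal run of frames with
#' no target loss lasting at least `min_len_s` seconds (default 100 s: a
#' 10 s averaging window needs at least ten consecutive heart-rate values
#' for comparison against a reference).
#'
#' @param loss_flags logical vector, one per frame, `TRUE` where the tracker
#'   lost the target.
#' @param frame_rate frames per second.
#' @param min_len_s minimum segment duration in seconds (default 100).
#' @return Data frame with columns `start_frame` and `end_frame` (1-based,
#'   inclusive); zero rows when no segment qualifies.
#' @export
qualify_segments <- function(loss_flags, frame_rate, min_len_s = 100) {
  stopifnot(is.logical(loss_flags), frame_rate > 0)
  if (length(loss_flags) == 0)
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  r <- rle(!loss_flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & (r$lengths / frame_rate >= min_len_s)
  data.frame(start_frame = starts[ok], end_frame = ends[ok])
}
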