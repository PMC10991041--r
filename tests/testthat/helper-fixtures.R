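# Small in-code fixtures shared across test files.

# A frame with all RGB channels equal, chosen so the luma channel equals
# `y_target` exactly under the default transform (offset 16, row sum
# 219.360 on [0,1] input).
frame_with_luma <- function(y_target, h = 4, w = 4) {
  rowsum1 <- sum(color_matrix("paper")$matrix[1, ])
  v <- (y_target - 16) * 255 / rowsum1
  array(rep(as.vector(v), 3), dim = c(h, w, 3))
}

sine_trace <- function(freq_hz, duration_s = 10, sample_rate = 25, amp = 1,
                       phase = 0) {
  t <- seq(0, duration_s - 1 / sample_rate, by = 1 / sample_rate)
  pulse_trace(amp * sin(2 * pi * freq_hz * t + phase), sample_rate)
}

# Power near f0 relative to the rest of the spectrum.
band_snr <- function(values, sample_rate, f0, half_width = 0.15) {
  sp <- primpulse:::.periodogram(values, sample_rate)
  inb <- sp$freq >= f0 - half_width & sp$freq <= f0 + half_width
  sum(sp$power[inb]) / sum(sp$power[!inb])
}

reconstruction_error <- function(dec, x) {
  rec <- dec$residual$values
  for (im in dec$imfs) rec <- rec + im$values
  max(abs(x - rec)) / max(abs(x))
}

# Hand-built imf_set (for exercising the selection rule on known content).
fake_imf_set <- function(traces, residual) {
  structure(list(imfs = traces, residual = residual,
                 params = list(method = "fixture")), class = "imf_set")
}
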