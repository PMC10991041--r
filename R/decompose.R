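#' Frequency band specifications
#'
#' Passband edges and filter order for the Butterworth band-pass. The
#' cardiac band is 1.5--4.2 Hz (90--250 beats per minute) and the
#' respiratory band 0.25--0.8 Hz (15--48 breaths per minute), both filtered
#' at third order.
#'
#' @param low_hz,high_hz passband edges in Hz, `0 < low < high`.
#' @param order filter order (default 3).
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(low_hz, high_hz, order = 3) {
  if (low_hz <= 0 || high_hz <= low_hz)
    .stopf("band edges must satisfy 0 < low < high")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "band_spec")
}

#' @rdname band_spec
#' @export
cardiac_band <- function() band_spec(1.5, 4.2, 3)

#' @rdname band_spec
#' @export
respiratory_band <- function() band_spec(0.25, 0.8, 3)

#' Zero-phase Butterworth band-pass
#'
#' Applies a Butterworth band-pass of the given order forward and backward
#' (`signal::filtfilt`), so the output is zero-phase: pulse peaks are not
#' shifted in time relative to a reference trace. Output length equals input
#' length.
#'
#' @param trace a [pulse_trace()].
#' @param band a [band_spec()]; default the cardiac band.
#' @return A filtered [pulse_trace()].
#' @export
bandpass <- function(trace, band = cardiac_band()) {
  stopifnot(inherits(trace, "pulse_trace"), inherits(band, "band_spec"))
  nyq <- trace$sample_rate / 2
  if (band$high_hz >= nyq)
    .stopf("band edge %.3g Hz is at or above Nyquist (%.3g Hz)",
           band$high_hz, nyq)
  if (length(trace$values) <= 3 * (band$order + 1))
    .stopf("trace too short (%d samples) for an order-%d band-pass",
           length(trace$values), band$order)
  bf <- signal::butter(band$order, c(band$low_hz, band$high_hz) / nyq,
                       type = "pass")
  out <- signal::filtfilt(bf, trace$values)
  pulse_trace(out, trace$sample_rate, trace$t0)
}

#' Empirical mode decomposition
#'
#' Decomposes a trace into intrinsic mode functions (IMFs) by sifting:
#' cubic-spline envelopes through the local maxima and minima (natural
#' splines, with up to two extrema mirrored past each end to control edge
#' effects), subtracting the mean envelope until the Cauchy criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2) < sift_tolerance` is met.
#' Extraction stops when the residual has fewer than two extrema (is
#' monotone) or `max_imfs` is reached. IMFs are ordered from highest to
#' lowest frequency; `sum(IMFs) + residual` reconstructs the input exactly
#' up to floating-point error.
#'
#' @param trace a [pulse_trace()] (length at least 8).
#' @param max_imfs maximum number of IMFs (default 9).
#' @param sift_tolerance Cauchy stopping tolerance (default 0.2).
#' @param max_sift maximum sifting iterations per IMF.
#' @return An object of class `imf_set`: list with `imfs` (list of
#'   [pulse_trace()], IMF 1 first), `residual` and `params`.
#' @export
emd <- function(trace, max_imfs = 9, sift_tolerance = 0.2, max_sift = 50) {
  stopifnot(inherits(trace, "pulse_trace"))
  x <- trace$values
  if (length(x) < 8) .stopf("trace too short for decomposition (need >= 8)")
  dec <- .cpp_emd(x, as.integer(max_imfs), sift_tolerance,
                  as.integer(max_sift))
  .as_imf_set(dec, trace, params = list(method = "emd",
                                        sift_tolerance = sift_tolerance))
}

.as_imf_set <- function(dec, trace, params) {
  k <- ncol(dec$imfs)
  imfs <- lapply(seq_len(k), function(j)
    pulse_trace(dec$imfs[, j], trace$sample_rate, trace$t0))
  structure(list(imfs = imfs,
                 residual = pulse_trace(dec$residual, trace$sample_rate,
                                        trace$t0),
                 params = params),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual (%s), %d samples @ %.6g Hz\n",
              length(x$imfs), x$params$method,
              length(x$residual$values), x$residual$sample_rate))
  invisible(x)
}

#' CEEMDAN decomposition
#'
#' Complete ensemble empirical mode decomposition with adaptive noise.
#' Stage 1 averages the first EMD mode of `ensemble_size` noise-perturbed
#' copies `x + b0 w_i` (white Gaussian `w_i`, `b0 = noise_std * sd(x)`).
#' At stage `k`, the residual is perturbed with the k-th EMD mode of each
#' noise realisation, `r_k + b_k E_k(w_i)` with `b_k = noise_std * sd(r_k)`,
#' and the ensemble mean of the first sifted mode becomes IMF `k + 1`.
#' Residuals are formed by subtraction, so `sum(IMFs) + residual`
#' reconstructs the input exactly ("complete"). The added noise cancels in
#' the ensemble mean, suppressing mode mixing caused by, e.g., illumination
#' flicker in the intensity trace.
#'
#' @inheritParams emd
#' @param noise_std noise amplitude relative to the running residual's
#'   standard deviation (default 0.2).
#' @param ensemble_size number of noise realisations (default 100).
#' @param seed optional RNG seed for the noise ensemble.
#' @return An `imf_set` (see [emd()]).
#' @export
ceemdan <- function(trace, noise_std = 0.2, ensemble_size = 100, seed = NULL,
                    max_imfs = 9, sift_tolerance = 0.2, max_sift = 50) {
  stopifnot(inherits(trace, "pulse_trace"))
  x <- trace$values
  n <- length(x)
  if (n < 8) .stopf("trace too short for decomposition (need >= 8)")
  if (ensemble_size < 2) .stopf("ensemble_size must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  sdx <- sd(x)
  if (sdx < 1e-12) {
    dec <- list(imfs = matrix(0, n, 0), residual = x)
    return(.as_imf_set(dec, trace, params = list(method = "ceemdan",
      noise_std = noise_std, ensemble_size = ensemble_size, seed = seed)))
  }
  M <- as.integer(ensemble_size)
  noise <- lapply(seq_len(M), function(i) rnorm(n))
  # pre-decompose each noise realisation once
  noise_modes <- lapply(noise, function(w)
    .cpp_emd(w, as.integer(max_imfs), sift_tolerance,
             as.integer(max_sift))$imfs)

  imfs <- list()
  res <- x
  for (k in seq_len(max_imfs)) {
    b <- noise_std * sd(res)
    acc <- numeric(n)
    n_ok <- 0L
    for (i in seq_len(M)) {
      wk <- if (k == 1) noise[[i]] * sdx    # stage 1 perturbs x directly
            else if (ncol(noise_modes[[i]]) >= k - 1) noise_modes[[i]][, k - 1]
            else NULL
      xi <- if (is.null(wk)) res else res + b * wk / max(sd(wk), 1e-12)
      s1 <- .cpp_sift1(xi, sift_tolerance, as.integer(max_sift))
      if (s1$ok) {
        acc <- acc + s1$imf
        n_ok <- n_ok + 1L
      }
    }
    if (n_ok == 0L) break   # residual monotone in every realisation
    d <- acc / n_ok
    imfs[[k]] <- d
    res <- res - d
    s_res <- .cpp_sift1(res, sift_tolerance, as.integer(max_sift))
    if (!s_res$ok) break    # residual has no oscillation left
  }
  K <- length(imfs)
  dec <- list(imfs = if (K) matrix(unlist(imfs), n, K) else matrix(0, n, 0),
              residual = res)
  .as_imf_set(dec, trace, params = list(method = "ceemdan",
    noise_std = noise_std, ensemble_size = ensemble_size, seed = seed,
    max_imfs = max_imfs))
}

#' Dominant frequency of a trace
#'
#' Frequency of the maximum of the Hann-windowed, mean-removed periodogram,
#' refined by parabolic interpolation around the peak bin.
#'
#' @param trace a [pulse_trace()], length at least 16, non-constant.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(trace) {
  stopifnot(inherits(trace, "pulse_trace"))
  x <- trace$values
  n <- length(x)
  if (n < 16) .stopf("trace too short for spectral estimation (need >= 16)")
  if (sd(x) < 1e-12)
    .stopf("dominant frequency undefined for a constant trace")
  sp <- .periodogram(x, trace$sample_rate)
  k <- which.max(sp$power)
  f <- sp$freq[k]
  if (k > 1 && k < length(sp$power)) {
    a <- sp$power[k - 1]; b <- sp$power[k]; c <- sp$power[k + 1]
    den <- a - 2 * b + c
    if (abs(den) > 1e-300) {
      delta <- 0.5 * (a - c) / den
      f <- f + delta * (sp$freq[2] - sp$freq[1])
    }
  }
  f
}

# Hann-windowed magnitude periodogram at positive frequencies.
.periodogram <- function(x, sample_rate) {
  n <- length(x)
  w <- .hann1(n)
  X <- fft((x - mean(x)) * w)
  nb <- floor(n / 2)
  list(freq = (1:nb) * sample_rate / n, power = Mod(X[2:(nb + 1)])^2)
}

#' Convert frequency to beats per minute
#'
#' `60 * f`: 1.7 Hz corresponds to 102 beats per minute, 1.8 Hz to 108.
#'
#' @param f_hz frequency in Hz (non-negative).
#' @return Beats (or breaths) per minute.
#' @export
hz_to_bpm <- function(f_hz) {
  if (any(f_hz < 0)) .stopf("frequency must be non-negative")
  60 * f_hz
}

#' Select the cardiac IMF
#'
#' Picks the IMF carrying the cardiac signal: among IMFs whose dominant
#' frequency lies in the cardiac band, the one with the greatest in-band
#' spectral power. Because the trace entering the decomposition has already
#' been band-passed to the cardiac band, this is IMF 1 in the nominal case;
#' the band constraint makes the choice robust when IMF 1 is residual
#' high-frequency noise.
#'
#' @param imf_set an `imf_set` from [emd()] or [ceemdan()].
#' @param band a [band_spec()]; default the cardiac band.
#' @return List with `index` (1-based IMF index) and `trace` (the selected
#'   [pulse_trace()]).
#' @export
select_cardiac_imf <- function(imf_set, band = cardiac_band()) {
  stopifnot(inherits(imf_set, "imf_set"))
  if (length(imf_set$imfs) < 1) .stopf("decomposition produced no IMFs")
  cand <- integer(0)
  power <- numeric(0)
  for (j in seq_along(imf_set$imfs)) {
    tr <- imf_set$imfs[[j]]
    f <- tryCatch(dominant_frequency(tr), error = function(e) NA_real_)
    if (is.na(f) || f < band$low_hz || f > band$high_hz) next
    sp <- .periodogram(tr$values, tr$sample_rate)
    inband <- sp$freq >= band$low_hz & sp$freq <= band$high_hz
    cand <- c(cand, j)
    power <- c(power, sum(sp$power[inband]))
  }
  if (length(cand) == 0)
    .stopf("no IMF has its dominant frequency in %.3g-%.3g Hz: no cardiac component",
           band$low_hz, band$high_hz)
  idx <- cand[which.max(power)]
  list(index = idx, trace = imf_set$imfs[[idx]])
}
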