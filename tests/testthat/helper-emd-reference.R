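# Independent reference implementation of the sifting decomposition, written
# against the same algorithm description as the package's compiled core but
# sharing no code with it: extrema by sign changes of the first difference,
# envelopes via stats::spline (natural cubic), up to two extrema mirrored
# about each end, Cauchy stopping criterion. Used as the oracle for the
# EMD/CEEMDAN equivalence checks.

ref_extrema <- function(x) {
  dx <- diff(x)
  s <- sign(dx)
  # interior indices (1-based) where the slope sign flips
  flips <- which(s[-1] != s[-length(s)] & s[-1] != 0 & s[-length(s)] != 0) + 1
  list(maxima = flips[dx[flips - 1] > 0], minima = flips[dx[flips - 1] < 0])
}

ref_envelope <- function(idx1, x) {
  n <- length(x)
  q <- idx1 - 1                     # 0-based knot positions
  nl <- min(2L, length(q))
  tk <- c(-rev(head(q, nl)), q, 2 * (n - 1) - rev(tail(q, nl)))
  yk <- c(rev(x[head(idx1, nl)]), x[idx1], rev(x[tail(idx1, nl)]))
  stats::spline(tk, yk, xout = 0:(n - 1), method = "natural")$y
}

ref_sift1 <- function(x, tol = 0.2, max_sift = 50) {
  ex <- ref_extrema(x)
  if (length(ex$maxima) + length(ex$minima) < 2 ||
      length(ex$maxima) == 0 || length(ex$minima) == 0)
    return(NULL)
  h <- x
  for (it in seq_len(max_sift)) {
    ex <- ref_extrema(h)
    if (length(ex$maxima) == 0 || length(ex$minima) == 0) break
    m <- (ref_envelope(ex$maxima, h) + ref_envelope(ex$minima, h)) / 2
    num <- sum(m^2)
    den <- sum(h^2)
    h <- h - m
    if (den <= 0 || num / den < tol) break
  }
  h
}

ref_emd <- function(x, max_imfs = 9, tol = 0.2, max_sift = 50) {
  res <- x
  imfs <- list()
  while (length(imfs) < max_imfs) {
    imf <- ref_sift1(res, tol, max_sift)
    if (is.null(imf)) break
    imfs[[length(imfs) + 1]] <- imf
    res <- res - imf
  }
  list(imfs = imfs, residual = res)
}

# Mirrors the package's ensemble logic (same RNG draws for a given seed) but
# runs entirely on the reference sifting above.
ref_ceemdan <- function(x, noise_std = 0.2, ensemble_size = 100, seed = 1,
                        max_imfs = 9, tol = 0.2, max_sift = 50) {
  n <- length(x)
  set.seed(seed)
  sdx <- sd(x)
  M <- ensemble_size
  noise <- lapply(seq_len(M), function(i) rnorm(n))
  noise_modes <- lapply(noise, function(w) ref_emd(w, max_imfs, tol,
                                                   max_sift)$imfs)
  imfs <- list()
  res <- x
  for (k in seq_len(max_imfs)) {
    b <- noise_std * sd(res)
    acc <- numeric(n)
    n_ok <- 0L
    for (i in seq_len(M)) {
      wk <- if (k == 1) noise[[i]] * sdx
            else if (length(noise_modes[[i]]) >= k - 1) noise_modes[[i]][[k - 1]]
            else NULL
      xi <- if (is.null(wk)) res else res + b * wk / max(sd(wk), 1e-12)
      s1 <- ref_sift1(xi, tol, max_sift)
      if (!is.null(s1)) {
        acc <- acc + s1
        n_ok <- n_ok + 1L
      }
    }
    if (n_ok == 0L) break
    d <- acc / n_ok
    imfs[[k]] <- d
    res <- res - d
    if (is.null(ref_sift1(res, tol, max_sift))) break
  }
  list(imfs = imfs, residual = res)
}
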