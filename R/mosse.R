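#' MOSSE correlation-filter tracking
#'
#' Stabilises the region of interest across frames so the intensity trace
#' follows the moving head. The filter minimises the output sum of squared
#' error between the correlation response and a desired Gaussian response.
#' In the Fourier domain the filter is `H* = A / B` with running accumulators
#' updated per frame as
#' `A_i = eta G (x) F_i* + (1 - eta) A_(i-1)` and
#' `B_i = eta F_i (x) F_i* + (1 - eta) B_(i-1)`,
#' where `F_i` is the preprocessed patch spectrum, `G` the Gaussian target
#' spectrum, `(x)` element-wise multiplication and `eta` the learning rate
#' (default 0.125). Tracking failure is declared when the peak-to-sidelobe
#' ratio (PSR) of the response falls below a threshold.
#'
#' @name mosse
NULL

.hann1 <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

.hann2 <- function(h, w) outer(.hann1(h), .hann1(w))

#' Preprocess a tracking patch
#'
#' Log transform (`log(1 + v)`), zero-mean unit-L2-norm normalisation, then
#' multiplication by a 2-D cosine (Hann) window. A constant patch has zero
#' norm and no usable structure; an all-zero patch is returned with a
#' warning.
#'
#' @param patch numeric matrix (Y-channel crop at the current box).
#' @param window optional precomputed Hann window of matching size.
#' @return Numeric matrix of the same size.
#' @export
mosse_preprocess <- function(patch, window = NULL) {
  if (is.null(window)) window <- .hann2(nrow(patch), ncol(patch))
  v <- log1p(patch)
  v <- v - mean(v)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) {
    .warnf("constant patch: preprocessing has no structure to normalise")
    return(v * 0)
  }
  (v / nv) * window
}

# Gaussian response image peaking at (cy, cx), 1-based.
.gauss_response <- function(h, w, cy, cx, sigma) {
  dy <- (1:h) - cy
  dx <- (1:w) - cx
  exp(-(outer(dy^2, dx^2, "+")) / (2 * sigma^2))
}

# Small random affine warp (rotation + isotropic scale about the centre),
# bilinear sampling with edge clamping.
.warp_patch <- function(patch, max_angle = 0.1, max_scale = 0.05) {
  h <- nrow(patch); w <- ncol(patch)
  a <- runif(1, -max_angle, max_angle)
  s <- 1 + runif(1, -max_scale, max_scale)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix((1:h) - cy, h, w)
  xx <- matrix((1:w) - cx, h, w, byrow = TRUE)
  sy <- (cos(a) * yy - sin(a) * xx) / s + cy
  sx <- (sin(a) * yy + cos(a) * xx) / s + cx
  sy <- pmin(pmax(sy, 1), h)
  sx <- pmin(pmax(sx, 1), w)
  y0 <- pmin(floor(sy), h - 1); x0 <- pmin(floor(sx), w - 1)
  fy <- sy - y0; fx <- sx - x0
  idx <- function(r, c) patch[cbind(as.vector(r), as.vector(c))]
  out <- (1 - fy) * (1 - fx) * idx(y0, x0) +
         (1 - fy) * fx       * idx(y0, x0 + 1) +
         fy       * (1 - fx) * idx(y0 + 1, x0) +
         fy       * fx       * idx(y0 + 1, x0 + 1)
  matrix(out, h, w)
}

# Crop the Y frame at a box, clamping the box inside the frame.
# Returns list(patch, box, clamped).
.crop_clamped <- function(y, box) {
  h <- nrow(y); w <- ncol(y)
  x <- min(max(box$x, 0L), w - box$width)
  yy <- min(max(box$y, 0L), h - box$height)
  clamped <- (x != box$x) || (yy != box$y)
  box2 <- bounding_box(x, yy, box$width, box$height)
  list(patch = .crop(y, box2), box = box2, clamped = clamped)
}

#' Initialise a MOSSE filter
#'
#' Builds the filter `H* = sum_i G (x) F_i* / sum_i F_i (x) F_i*` over
#' `n_augmentations` training patches: the exact initial crop plus small
#' random affine warps of it. `G` is the spectrum of a 2-D Gaussian of
#' standard deviation `target_sigma` centred on the patch.
#'
#' @param frame_y numeric matrix: the Y channel of the first frame.
#' @param box initial [bounding_box()].
#' @param n_augmentations number of training patches (first one unwarped).
#' @param target_sigma Gaussian response standard deviation in pixels.
#' @param eta learning rate for subsequent updates (default 0.125).
#' @param eps denominator regularisation.
#' @param seed optional RNG seed for the random warps.
#' @return An object of class `mosse_state`.
#' @export
mosse_init <- function(frame_y, box, n_augmentations = 8, target_sigma = 2,
                       eta = 0.125, eps = 1e-5, seed = NULL) {
  box <- .as_box(box)
  .check_box_in(box, dim(frame_y))
  if (eta <= 0 || eta > 1) .stopf("eta must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  patch <- .crop(frame_y, box)
  if (sd(patch) < 1e-12) .stopf("cannot initialise tracker on a constant patch")
  h <- box$height; w <- box$width
  win <- .hann2(h, w)
  cy <- floor(h / 2) + 1; cx <- floor(w / 2) + 1
  G <- fft(.gauss_response(h, w, cy, cx, target_sigma))
  A <- matrix(0 + 0i, h, w); B <- matrix(0 + 0i, h, w)
  for (k in seq_len(n_augmentations)) {
    p <- if (k == 1) patch else .warp_patch(patch)
    Fi <- fft(mosse_preprocess(p, win))
    A <- A + G * Conj(Fi)
    B <- B + Fi * Conj(Fi)
  }
  structure(list(A = A, B = B, G = G, window = win, eta = eta,
                 target_sigma = target_sigma, eps = eps, box = box,
                 centre = c(cy, cx)), class = "mosse_state")
}

# Correlation response of the filter on a preprocessed patch spectrum.
.mosse_response <- function(state, Fi) {
  H <- state$A / (state$B + state$eps)
  Re(fft(H * Fi, inverse = TRUE)) / length(Fi)
}

# Peak-to-sidelobe ratio; sidelobe excludes an 11x11 window around the peak.
.psr <- function(resp, peak_rc, excl = 5) {
  h <- nrow(resp); w <- ncol(resp)
  ry <- max(1, peak_rc[1] - excl):min(h, peak_rc[1] + excl)
  rx <- max(1, peak_rc[2] - excl):min(w, peak_rc[2] + excl)
  mask <- matrix(TRUE, h, w)
  mask[ry, rx] <- FALSE
  side <- resp[mask]
  s <- sd(side)
  if (s < 1e-12) return(Inf)
  (resp[peak_rc[1], peak_rc[2]] - mean(side)) / s
}

# Wrap a circular displacement into [-n/2, n/2).
.wrap_disp <- function(d, n) {
  if (d >= n / 2) d - n else if (d < -n / 2) d + n else d
}

#' Advance the tracker by one frame
#'
#' Correlates the patch at the previous box with the current filter; the new
#' box centre is the previous centre plus the response-peak displacement.
#' The accumulators are then updated with the patch at the new location:
#' with `eta = 1` the filter forgets its history and equals a fresh
#' single-patch initialisation (memoryless limit).
#'
#' @param state a `mosse_state` from [mosse_init()].
#' @param frame_y numeric matrix: Y channel of the next frame.
#' @return List with elements `state` (updated), `box` (new
#'   [bounding_box()]), `psr` and `at_boundary` (logical: the box had to be
#'   clamped inside the frame).
#' @export
mosse_step <- function(state, frame_y) {
  stopifnot(inherits(state, "mosse_state"))
  cc <- .crop_clamped(frame_y, state$box)
  Fi <- fft(mosse_preprocess(cc$patch, state$window))
  resp <- .mosse_response(state, Fi)
  pk <- which(resp == max(resp), arr.ind = TRUE)[1, ]
  psr <- .psr(resp, pk)
  dy <- .wrap_disp(pk[1] - state$centre[1], nrow(resp))
  dx <- .wrap_disp(pk[2] - state$centre[2], ncol(resp))
  newbox <- list(x = cc$box$x + dx, y = cc$box$y + dy,
                 width = state$box$width, height = state$box$height)
  h <- nrow(frame_y); w <- ncol(frame_y)
  at_boundary <- newbox$x < 0 || newbox$y < 0 ||
    newbox$x + newbox$width > w || newbox$y + newbox$height > h ||
    cc$clamped
  newbox$x <- min(max(newbox$x, 0L), w - newbox$width)
  newbox$y <- min(max(newbox$y, 0L), h - newbox$height)
  newbox <- bounding_box(newbox$x, newbox$y, newbox$width, newbox$height)
  # update with the patch at the NEW location
  p2 <- .crop(frame_y, newbox)
  F2 <- fft(mosse_preprocess(p2, state$window))
  eta <- state$eta
  state$A <- eta * (state$G * Conj(F2)) + (1 - eta) * state$A
  state$B <- eta * (F2 * Conj(F2)) + (1 - eta) * state$B
  state$box <- newbox
  list(state = state, box = newbox, psr = psr, at_boundary = at_boundary)
}

#' Track a region of interest through a frame sequence
#'
#' Runs [mosse_init()] on the first frame and [mosse_step()] on each
#' subsequent frame. Frames whose response PSR falls below `psr_threshold`
#' (or where the box had to be clamped at the frame boundary) are flagged as
#' target loss; segment qualification uses these flags.
#'
#' @param fs a [frame_sequence()].
#' @param initial_box [bounding_box()] on the first frame.
#' @param eta learning rate (default 0.125).
#' @param psr_threshold PSR below which the target is declared lost.
#' @param cm [color_matrix()] used for the Y channel.
#' @param ... further arguments to [mosse_init()].
#' @return A data frame with one row per frame: `frame`, `x`, `y`, `width`,
#'   `height`, `psr`, `lost`.
#' @export
mosse_track <- function(fs, initial_box, eta = 0.125, psr_threshold = 5,
                        cm = color_matrix(), ...) {
  te <- .track_extract(fs, initial_box, track = TRUE, eta = eta,
                       psr_threshold = psr_threshold, cm = cm, ...)
  te$boxes
}

# Single pass over the frames: track (optionally) and extract the ROI mean
# luma trace. Lazy frame sequences are only materialised one frame at a time.
# `seed` (forwarded to mosse_init) keeps the augmentation warps, and hence
# the whole run, reproducible.
.track_extract <- function(fs, initial_box, track = TRUE, eta = 0.125,
                           psr_threshold = 5, cm = color_matrix(), ...) {
  stopifnot(inherits(fs, "frame_sequence"))
  box <- .as_box(initial_box)
  .check_box_in(box, fs$dim)
  n <- fs$n_frames
  xs <- integer(n); ys <- integer(n)
  psr <- rep(NA_real_, n); lost <- logical(n); vals <- numeric(n)
  state <- NULL
  for (i in seq_len(n)) {
    y <- .frame_luma(get_frame(fs, i), cm)
    if (track) {
      if (i == 1) {
        state <- mosse_init(y, box, eta = eta, ...)
      } else {
        st <- mosse_step(state, y)
        state <- st$state
        box <- st$box
        psr[i] <- st$psr
        lost[i] <- st$psr < psr_threshold || st$at_boundary
      }
    }
    xs[i] <- box$x; ys[i] <- box$y
    vals[i] <- mean(.crop(y, box))
  }
  boxes <- data.frame(frame = seq_len(n), x = xs, y = ys,
                      width = box$width, height = box$height,
                      psr = psr, lost = lost)
  list(boxes = boxes,
       trace = pulse_trace(vals, sample_rate = fs$frame_rate))
}
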