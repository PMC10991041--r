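#' Frame sequences
#'
#' A `frame_sequence` is an ordered stack of RGB frames plus its frame rate.
#' Pixel values are held on the canonical real-valued 0--255 scale (inputs on
#' 0--1 are rescaled on ingestion). Frames may be stored in memory (a list of
#' `height x width x 3` arrays) or generated on demand from a frame function,
#' which keeps long synthetic videos cheap: only one frame is materialised at
#' a time.
#'
#' @param frames list of `h x w x 3` arrays (or `h x w` matrices, replicated
#'   across channels with a warning), values 0--255 or 0--1.
#' @param frame_rate frames per second; must be positive.
#' @param frame_fn alternative to `frames`: a function `f(i)` returning frame
#'   `i` (1-based) as an `h x w x 3` array on the 0--255 scale.
#' @param n_frames number of frames (required with `frame_fn`).
#' @param dim frame dimensions `c(height, width)` (required with `frame_fn`).
#' @return An object of class `frame_sequence`.
#' @examples
#' f <- array(128, dim = c(4, 6, 3))
#' fs <- frame_sequence(list(f, f), frame_rate = 25)
#' n_frames(fs)
#' @export
frame_sequence <- function(frames = NULL, frame_rate, frame_fn = NULL,
                           n_frames = NULL, dim = NULL) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    .stopf("frame_rate must be a single positive number")
  if (!is.null(frame_fn)) {
    if (is.null(n_frames) || is.null(dim))
      .stopf("frame_fn requires n_frames and dim = c(height, width)")
    obj <- list(frames = NULL, frame_fn = frame_fn,
                n_frames = as.integer(n_frames), dim = as.integer(dim[1:2]),
                frame_rate = frame_rate, value_range = "0-255")
    class(obj) <- "frame_sequence"
    return(obj)
  }
  if (!is.list(frames) || length(frames) == 0)
    .stopf("frames must be a non-empty list of arrays")
  frames <- lapply(frames, .canonical_frame)
  d0 <- dim(frames[[1]])[1:2]
  for (i in seq_along(frames)) {
    if (!all(dim(frames[[i]])[1:2] == d0))
      .stopf("frame %d has dimensions %dx%d; expected %dx%d", i,
             dim(frames[[i]])[1], dim(frames[[i]])[2], d0[1], d0[2])
  }
  obj <- list(frames = frames, frame_fn = NULL,
              n_frames = length(frames), dim = as.integer(d0),
              frame_rate = frame_rate, value_range = "0-255")
  class(obj) <- "frame_sequence"
  obj
}

# Coerce one frame to h x w x 3 on the 0-255 scale.
.canonical_frame <- function(f) {
  if (is.matrix(f)) {
    .warnf("grayscale frame replicated across three RGB channels")
    f <- array(rep(f, 3), dim = c(dim(f), 3))
  }
  if (length(dim(f)) != 3 || dim(f)[3] != 3)
    .stopf("a frame must be a height x width x 3 array (got dims %s)",
           paste(dim(f), collapse = "x"))
  if (max(f) <= 1 && min(f) >= 0) f <- f * 255
  f
}

#' @rdname frame_sequence
#' @param fs a `frame_sequence`.
#' @param i frame index (1-based).
#' @export
get_frame <- function(fs, i) {
  stopifnot(inherits(fs, "frame_sequence"))
  if (i < 1 || i > fs$n_frames) .stopf("frame index %d out of range 1..%d",
                                       i, fs$n_frames)
  if (!is.null(fs$frame_fn)) fs$frame_fn(i) else fs$frames[[i]]
}

#' @rdname frame_sequence
#' @export
n_frames <- function(fs) {
  stopifnot(inherits(fs, "frame_sequence"))
  fs$n_frames
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.6g fps (%s)%s\n",
              x$n_frames, x$dim[1], x$dim[2], x$frame_rate,
              x$value_range, if (is.null(x$frames)) ", lazy" else ""))
  invisible(x)
}

#' Read a video as a frame sequence
#'
#' Reads a directory of sequentially numbered PNG frames (lexicographic
#' order). Compressed video containers (MP4/AVI) are not decodable with the
#' packages this package builds on; decode them to a frame directory first
#' (e.g. `ffmpeg -i in.mp4 frames/%06d.png`). Frame directories carry no
#' embedded frame rate, so `frame_rate` is mandatory.
#'
#' @param path directory containing `.png` frames.
#' @param frame_rate frames per second of the source video.
#' @param lazy if `TRUE` (default) frames are decoded on demand.
#' @return A [frame_sequence()].
#' @export
read_video <- function(path, frame_rate = NULL, lazy = TRUE) {
  if (!file.exists(path)) .stopf("cannot read video input '%s': no such path", path)
  if (!dir.exists(path)) {
    .stopf(paste0("'%s' is not a frame directory; compressed containers ",
                  "(mp4/avi) are not supported -- decode to PNG frames first"),
           path)
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) .stopf("frame directory '%s' contains no .png frames", path)
  if (is.null(frame_rate))
    .stopf("frame directories carry no frame rate; supply frame_rate")
  read1 <- function(i) {
    img <- png::readPNG(files[i])
    if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
    if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
    img * 255
  }
  f1 <- read1(1)
  if (lazy) {
    frame_sequence(frame_fn = read1, n_frames = length(files),
                   dim = dim(f1)[1:2], frame_rate = frame_rate)
  } else {
    frame_sequence(lapply(seq_along(files), read1), frame_rate = frame_rate)
  }
}

#' Write a frame sequence as a PNG frame directory
#'
#' Lossless round trip: `read_video(write_video(fs, d), frame_rate)` returns
#' the same frames up to 8-bit quantization (exactly, when the input is
#' already integer-valued on 0--255).
#'
#' @param fs a [frame_sequence()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_video <- function(fs, path) {
  stopifnot(inherits(fs, "frame_sequence"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(fs$n_frames)) {
    f <- pmin(pmax(get_frame(fs, i) / 255, 0), 1)
    png::writePNG(f, file.path(path, sprintf("frame_%06d.png", i)))
  }
  invisible(path)
}

#' Bounding boxes
#'
#' Rectangular region of interest in pixel coordinates: 0-based top-left
#' corner, half-open extent `[x, x + width) x [y, y + height)`. A box at
#' `(0, 0, w, h)` over a frame selects exactly `w * h` pixels.
#'
#' @param x,y top-left corner (0-based pixels; `x` is the column axis).
#' @param width,height extent in pixels, at least 1.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(x, y, width, height) {
  v <- c(x = x, y = y, width = width, height = height)
  if (any(v != floor(v))) .stopf("bounding box coordinates must be integers")
  if (width < 1 || height < 1) .stopf("bounding box extent must be >= 1 px")
  if (x < 0 || y < 0) .stopf("bounding box corner must be non-negative")
  structure(as.list(as.integer(v)), names = names(v), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> x=%d y=%d %dx%d\n",
              x$x, x$y, x$width, x$height))
  invisible(x)
}

.as_box <- function(b) {
  if (inherits(b, "bounding_box")) return(b)
  if (is.numeric(b) && length(b) == 4)
    return(bounding_box(b[1], b[2], b[3], b[4]))
  .stopf("expected a bounding_box or a numeric c(x, y, width, height)")
}

.check_box_in <- function(box, dim, frame_index = NA) {
  if (box$x + box$width > dim[2] || box$y + box$height > dim[1]) {
    where <- if (is.na(frame_index)) "" else sprintf(" at frame %d", frame_index)
    .stopf("bounding box (%d,%d,%d,%d) exceeds %dx%d frame%s",
           box$x, box$y, box$width, box$height, dim[1], dim[2], where)
  }
  invisible(TRUE)
}

# Crop a matrix (h x w) to a box; 0-based half-open box -> 1-based R slices.
.crop <- function(m, box) {
  m[(box$y + 1):(box$y + box$height), (box$x + 1):(box$x + box$width),
    drop = FALSE]
}

#' Uniformly sampled traces
#'
#' A `pulse_trace` holds a uniformly sampled 1-D signal: values, sampling
#' rate in Hz and start time in seconds. It carries the ROI mean-intensity
#' signal and everything derived from it (band-passed signals, IMFs,
#' reference PPG waveforms).
#'
#' @param values numeric vector, length at least 1.
#' @param sample_rate sampling rate in Hz, positive.
#' @param t0 start time in seconds (default 0).
#' @return An object of class `pulse_trace`.
#' @examples
#' tr <- pulse_trace(sin(2 * pi * 2 * (0:249) / 25), sample_rate = 25)
#' trace_times(tr)[1:3]
#' @export
pulse_trace <- function(values, sample_rate, t0 = 0) {
  if (length(values) < 1) .stopf("a trace needs at least one sample")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    .stopf("sample_rate must be positive")
  structure(list(values = as.numeric(values), sample_rate = sample_rate,
                 t0 = t0), class = "pulse_trace")
}

#' @rdname pulse_trace
#' @param trace a `pulse_trace`.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "pulse_trace"))
  trace$t0 + (seq_along(trace$values) - 1) / trace$sample_rate
}

#' @export
print.pulse_trace <- function(x, ...) {
  cat(sprintf("<pulse_trace> %d samples @ %.6g Hz, t0=%.6g s (%.6g s long)\n",
              length(x$values), x$sample_rate, x$t0,
              length(x$values) / x$sample_rate))
  invisible(x)
}

#' @export
length.pulse_trace <- function(x) length(x$values)

#' Read and write traces as delimited text
#'
#' Traces are exchanged as CSV with a `time_s,value` header. Values are
#' written with 15 significant digits so that `read_trace(write_trace(x))`
#' reproduces them to at least 12 significant digits.
#'
#' @param trace a [pulse_trace()].
#' @param path CSV file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [pulse_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pulse_trace"))
  df <- data.frame(time_s = sprintf("%.15g", trace_times(trace)),
                   value = sprintf("%.15g", trace$values))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) .stopf("cannot read trace '%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) .stopf("trace file '%s' has no data rows (line 1)", path)
  df <- tryCatch(read.csv(path), error = function(e)
    .stopf("cannot parse trace '%s': %s", path, conditionMessage(e)))
  if (!all(c("time_s", "value") %in% names(df)))
    .stopf("trace '%s' lacks time_s,value header (line 1)", path)
  tv <- suppressWarnings(as.numeric(df$time_s))
  vv <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.finite(tv) | !is.finite(vv))
  if (length(bad) > 0)
    .stopf("trace '%s': non-numeric entry at line %d", path, bad[1] + 1)
  df <- data.frame(time_s = tv, value = vv)
  n <- nrow(df)
  if (n == 1) return(pulse_trace(df$value, sample_rate = 1, t0 = df$time_s[1]))
  dt <- diff(df$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * mean(dt))
    .stopf("trace '%s' is not uniformly sampled", path)
  sr <- (n - 1) / (df$time_s[n] - df$time_s[1])
  pulse_trace(df$value, sample_rate = sr, t0 = df$time_s[1])
}
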