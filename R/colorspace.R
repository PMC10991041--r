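#' YCbCr color transform
#'
#' The luma/chroma transform separating intensity (Y) from color (Cb, Cr).
#' The matrix multiplies RGB normalised to [0, 1]; the offset vector
#' (16, 128, 128) is on the 8-bit scale, so Y lands in [16, 235].
#'
#' Two presets are provided. `"paper"` (the default) uses the coefficient
#' set this pipeline was described with, which departs from ITU-R BT.601 in
#' three entries (65.841 vs 65.481, -39.797 vs -37.797, -18.2214 vs -18.214).
#' `"bt601"` is the standard matrix. The difference is immaterial downstream
#' because only the temporal variation of Y is used.
#'
#' @param preset `"paper"` or `"bt601"`, ignored when `matrix` is given.
#' @param matrix optional explicit 3x3 coefficient matrix (rows Y, Cb, Cr).
#' @param offset optional 3-vector offset (default `c(16, 128, 128)`).
#' @return An object of class `color_matrix`.
#' @export
color_matrix <- function(preset = c("paper", "bt601"), matrix = NULL,
                         offset = NULL) {
  if (is.null(matrix)) {
    preset <- match.arg(preset)
    matrix <- switch(preset,
      paper = rbind(c(65.841, 128.553, 24.966),
                    c(-39.797, -74.203, 112),
                    c(112, -93.786, -18.2214)),
      bt601 = rbind(c(65.481, 128.553, 24.966),
                    c(-37.797, -74.203, 112),
                    c(112, -93.786, -18.214)))
  } else {
    matrix <- base::matrix(as.numeric(matrix), 3, 3)
    preset <- "custom"
  }
  if (is.null(offset)) offset <- c(16, 128, 128)
  if (length(offset) != 3) .stopf("offset must have 3 entries")
  structure(list(matrix = matrix, offset = as.numeric(offset),
                 preset = preset), class = "color_matrix")
}

#' @export
print.color_matrix <- function(x, ...) {
  cat(sprintf("<color_matrix> preset '%s'\n", x$preset))
  print(x$matrix)
  cat("offset:", x$offset, "\n")
  invisible(x)
}

#' Convert an RGB frame to YCbCr
#'
#' Per pixel, `[Y, Cb, Cr] = M [R, G, B]/255 + offset`, with `M` and the
#' offset from [color_matrix()]. Input frames are on the canonical 0--255
#' scale; equal R=G=B=0 maps to (16, 128, 128).
#'
#' @param frame `h x w x 3` RGB array on the 0--255 scale.
#' @param cm a [color_matrix()].
#' @return `h x w x 3` array with channels Y, Cb, Cr.
#' @examples
#' f <- array(0, dim = c(2, 2, 3))
#' rgb_to_ycbcr(f)[1, 1, ]  # 16 128 128
#' @export
rgb_to_ycbcr <- function(frame, cm = color_matrix()) {
  if (length(dim(frame)) != 3 || dim(frame)[3] != 3)
    .stopf("frame must be height x width x 3 (got dims %s)",
           paste(dim(frame), collapse = "x"))
  d <- dim(frame)
  out <- array(0, dim = d)
  M <- cm$matrix
  for (k in 1:3) {
    out[, , k] <- (M[k, 1] * frame[, , 1] + M[k, 2] * frame[, , 2] +
                   M[k, 3] * frame[, , 3]) / 255 + cm$offset[k]
  }
  out
}

# Y channel only (hot path: called once per frame).
.frame_luma <- function(frame, cm) {
  M <- cm$matrix
  (M[1, 1] * frame[, , 1] + M[1, 2] * frame[, , 2] +
   M[1, 3] * frame[, , 3]) / 255 + cm$offset[1]
}

#' ROI mean-intensity trace
#'
#' The raw motion signal: for each frame `t`, the mean of the luma (Y)
#' channel over the region of interest,
#' `i_Y(t) = sum_(x,y in ROI) I(x, y, t) / |ROI|`. The trace's sampling rate
#' is the video frame rate. Only Y feeds downstream processing; Cb and Cr
#' carry color and are unused.
#'
#' @param fs a [frame_sequence()].
#' @param boxes a single [bounding_box()] (fixed ROI) or a list with one box
#'   per frame (tracked ROI).
#' @param cm a [color_matrix()].
#' @return A [pulse_trace()] at the video frame rate.
#' @export
roi_mean_intensity <- function(fs, boxes, cm = color_matrix()) {
  stopifnot(inherits(fs, "frame_sequence"))
  n <- fs$n_frames
  if (inherits(boxes, "bounding_box") ||
      (is.numeric(boxes) && length(boxes) == 4)) {
    boxes <- rep(list(.as_box(boxes)), n)
  }
  if (length(boxes) != n)
    .stopf("need one box per frame (%d boxes for %d frames)", length(boxes), n)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    box <- .as_box(boxes[[i]])
    .check_box_in(box, fs$dim, frame_index = i)
    y <- .frame_luma(get_frame(fs, i), cm)
    vals[i] <- mean(.crop(y, box))
  }
  pulse_trace(vals, sample_rate = fs$frame_rate)
}
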