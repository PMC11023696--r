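#' Time-lapse image stack
#'
#' Container for a single-channel fluorescence stack stored as a
#' `frames x Y x X` array with its pixel size and frame rate. Intensities
#' are arbitrary fluorescence units; after background subtraction values
#' may legitimately go negative (noise), and downstream code tolerates
#' that.
#'
#' @param data numeric array with `dim = c(frames, ny, nx)`.
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @param frame_rate acquisition rate in Hz (> 0).
#' @param channel label.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size, frame_rate, channel = "TexasRed") {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be a frames x Y x X array", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be positive (micrometres)", call. = FALSE)
  }
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("`frame_rate` must be positive (Hz)", call. = FALSE)
  }
  structure(
    list(data = data, pixel_size = pixel_size, frame_rate = frame_rate,
         channel = channel),
    class = "image_stack"
  )
}

#' Number of frames in a stack
#' @param x an [image_stack()].
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  dim(x$data)[1]
}

#' Frame times of a stack in seconds
#' @param x an [image_stack()].
#' @export
frame_times <- function(x) {
  (seq_len(n_frames(x)) - 1L) / x$frame_rate
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> '%s': %d frames of %d x %d px (%.2f um/px) @ %g Hz\n",
              x$channel, d[1], d[2], d[3], x$pixel_size, x$frame_rate))
  invisible(x)
}

#' Rectangular pixel region of interest
#'
#' @param rows integer range of row (Y) indices.
#' @param cols integer range of column (X) indices.
#' @return list with validated `rows` and `cols`, class `pixel_roi`.
#' @export
pixel_roi <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(length(rows) >= 1, length(cols) >= 1, all(rows >= 1), all(cols >= 1))
  structure(list(rows = rows, cols = cols), class = "pixel_roi")
}

check_roi <- function(roi, dim_yx, what = "ROI") {
  if (!inherits(roi, "pixel_roi")) stop(sprintf("%s must be a pixel_roi", what), call. = FALSE)
  if (max(roi$rows) > dim_yx[1] || max(roi$cols) > dim_yx[2]) {
    stop(sprintf("%s lies outside the %d x %d frame", what, dim_yx[1], dim_yx[2]),
         call. = FALSE)
  }
  invisible(roi)
}

#' Mean intensity of an ROI over time
#'
#' @param stack an [image_stack()].
#' @param roi a [pixel_roi()].
#' @return a [trace_series()] of the per-frame ROI mean at the stack's
#'   frame rate.
#' @export
roi_mean_trace <- function(stack, roi) {
  stopifnot(inherits(stack, "image_stack"))
  check_roi(roi, dim(stack$data)[2:3])
  v <- apply(stack$data[, roi$rows, roi$cols, drop = FALSE], 1, mean)
  trace_series(v, stack$frame_rate, channel = stack$channel)
}
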