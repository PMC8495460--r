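#' Time-resolved single-channel image stack
#'
#' A `dynamic_stack` is the central imaging container: a height x width x time
#' array of intensities for one wavelength channel, plus the acquisition frame
#' interval. Frames are stored in acquisition order; pixel coordinates are
#' row-major with origin at the top-left corner (row 1, column 1).
#'
#' @param data numeric array of dimension `c(height, width, n_frames)`, or a
#'   matrix (interpreted as a single frame).
#' @param frame_interval time between consecutive frames, in seconds.
#' @param channel optional channel name (e.g. `"icg"`, `"anatomy"`).
#' @return An object of class `dynamic_stack`.
#' @examples
#' st <- dynamic_stack(array(rnorm(8 * 8 * 5), c(8, 8, 5)), frame_interval = 15)
#' n_frames(st)
#' @export
dynamic_stack <- function(data, frame_interval, channel = NULL) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "`data` must be a height x width x time array")
  assert_that(is.numeric(frame_interval) && length(frame_interval) == 1L &&
                frame_interval > 0,
              "`frame_interval` must be a single positive number of seconds")
  structure(
    list(data = data, frame_interval = as.numeric(frame_interval),
         channel = channel),
    class = "dynamic_stack"
  )
}

#' @rdname dynamic_stack
#' @param x a `dynamic_stack`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, c("dynamic_stack", "zstack")))
  dim(x$data)[3L]
}

#' Extract one frame of a stack as a matrix
#'
#' @param x a `dynamic_stack` or `zstack`.
#' @param i frame index (1-based).
#' @return A height x width matrix.
#' @export
get_frame <- function(x, i) {
  stopifnot(inherits(x, c("dynamic_stack", "zstack")))
  assert_that(i >= 1L && i <= dim(x$data)[3L], "frame index out of range")
  x$data[, , i]
}

#' @export
print.dynamic_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_stack%s> %d x %d px, %d frames @ %g s (%.1f min total)\n",
              if (is.null(x$channel)) "" else paste0(" ", x$channel),
              d[1], d[2], d[3], x$frame_interval,
              d[3] * x$frame_interval / 60))
  invisible(x)
}

#' @export
dim.dynamic_stack <- function(x) dim(x$data)

#' Frame acquisition times
#'
#' @param x a `dynamic_stack` or `zstack`.
#' @param unit `"s"` or `"min"`.
#' @return Numeric vector of frame start times, first frame at 0.
#' @export
frame_times <- function(x, unit = c("s", "min")) {
  unit <- match.arg(unit)
  t_s <- (seq_len(n_frames(x)) - 1L) * x$frame_interval
  if (unit == "min") t_s / 60 else t_s
}
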