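#' Construct a high-gamma feature stream
#'
#' A feature stream is the universal input to detection and classification: a
#' frames-by-electrodes matrix of clipped high-gamma z-scores together with its
#' frame rate and time origin.
#'
#' @param values Numeric matrix, frames x electrodes.
#' @param frame_rate Frames per second (Hz).
#' @param t0 Time (seconds) of the first frame. Default 0.
#' @param clip Absolute clip bound the values are expected to respect.
#'
#' @return A `feature_stream`: the matrix with attributes `frame_rate` and
#'   `t0`.
#' @export
feature_stream <- function(values, frame_rate, t0 = 0, clip = 3.5) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    abort("feature stream values must be finite numerics")
  }
  if (frame_rate <= 0) abort("frame_rate must be positive")
  if (any(abs(values) > clip + 1e-9)) {
    abort(sprintf("feature stream values must lie within [-%g, %g]", clip, clip))
  }
  structure(values, frame_rate = frame_rate, t0 = t0,
            class = c("feature_stream", "matrix", "array"))
}

#' @export
print.feature_stream <- function(x, ...) {
  cat(sprintf("<feature_stream> %d frames x %d electrodes @ %.4f Hz (t0 = %.3f s)\n",
              nrow(x), ncol(x), frame_rate(x), attr(x, "t0")))
  invisible(x)
}

#' Frame rate of a feature stream
#' @param x A `feature_stream`.
#' @return Frames per second.
#' @export
frame_rate <- function(x) attr(x, "frame_rate")

#' Number of frames in a feature stream
#' @param x A `feature_stream`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) nrow(x)

# Map times (s) to 1-based frame indices under the half-open convention
# frame f <-> [ (f-1)/rate, f/rate ) relative to t0.
time_to_frame <- function(x, t) {
  pmax(1L, pmin(nrow(x), as.integer(floor((t - attr(x, "t0")) * frame_rate(x))) + 1L))
}

frame_to_time <- function(x, f) attr(x, "t0") + (f - 1L) / frame_rate(x)

# Plain-matrix view (drops the class so base matrix ops stay fast).
fs_values <- function(x) {
  attr(x, "frame_rate") <- NULL
  attr(x, "t0") <- NULL
  class(x) <- NULL
  x
}
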