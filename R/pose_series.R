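#' Construct a pose series
#'
#' A `pose_series` is a uniformly sampled sequence of 2D infant poses: for
#' each frame, 17 keypoints in COCO-17 order with pixel coordinates and a
#' detection confidence in \[0, 1\]. It is the raw input to
#' [motion_series()]. Missing detections are encoded by confidence 0 (with
#' whatever coordinates the producer repeats), never by non-finite
#' coordinates.
#'
#' @param video_id Identifier string for the source video.
#' @param time_s Numeric vector of frame timestamps in seconds from video
#'   start, strictly increasing and uniformly spaced.
#' @param x,y Numeric matrices, frames x 17, of pixel coordinates.
#' @param confidence Numeric matrix, frames x 17, of scores in \[0, 1\].
#' @param sample_rate_hz Sampling rate in frames per second. If `NULL`,
#'   inferred from the median timestamp gap.
#' @param frame_width_px,frame_height_px Optional frame dimensions in pixels.
#' @return An object of class `pose_series`.
#' @seealso [read_pose_table()], [resample()], [motion_series()]
#' @export
#' @examples
#' n <- 5
#' ps <- pose_series(
#'   "demo", time_s = 0:(n - 1),
#'   x = matrix(100, n, 17), y = matrix(200, n, 17),
#'   confidence = matrix(1, n, 17)
#' )
#' ps
pose_series <- function(video_id, time_s, x, y, confidence,
                        sample_rate_hz = NULL,
                        frame_width_px = NULL, frame_height_px = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  confidence <- as.matrix(confidence)
  time_s <- as.numeric(time_s)
  if (is.null(sample_rate_hz)) {
    if (length(time_s) < 2L) {
      stop_gmaselect("cannot infer sample rate from fewer than 2 frames",
                     "gmaselect_sampling_error")
    }
    sample_rate_hz <- 1 / stats::median(diff(time_s))
  }
  obj <- structure(
    list(
      video_id = as.character(video_id),
      time_s = time_s,
      x = x, y = y, confidence = confidence,
      sample_rate_hz = as.numeric(sample_rate_hz),
      frame_width_px = frame_width_px,
      frame_height_px = frame_height_px
    ),
    class = "pose_series"
  )
  validate_pose_series(obj)
}

#' Validate a pose series
#'
#' Checks every `pose_series` invariant: exactly 17 keypoints, finite
#' coordinates, confidences in \[0, 1\], non-negative strictly increasing
#' timestamps with uniform gaps of 1/`sample_rate_hz` (tolerance 1e-6 s),
#' and at least 2 frames. Parsers call this so that no invalid object can
#' escape them.
#'
#' @param obj A `pose_series`.
#' @return `obj`, invisibly unchanged, if valid; otherwise a classed error.
#' @export
validate_pose_series <- function(obj) {
  n <- length(obj$time_s)
  if (n < 2L) {
    stop_gmaselect("a pose series needs at least 2 frames",
                   "gmaselect_schema_error")
  }
  for (fld in c("x", "y", "confidence")) {
    m <- obj[[fld]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != N_KEYPOINTS) {
      stop_gmaselect(
        sprintf("'%s' must be a %d x 17 numeric matrix", fld, n),
        "gmaselect_schema_error"
      )
    }
    if (!all(is.finite(m))) {
      stop_gmaselect(sprintf("non-finite values in '%s'", fld),
                     "gmaselect_schema_error")
    }
  }
  if (any(obj$confidence < 0 | obj$confidence > 1)) {
    stop_gmaselect("confidence values must lie in [0, 1]",
                   "gmaselect_schema_error")
  }
  if (any(obj$time_s < 0)) {
    stop_gmaselect("timestamps must be >= 0", "gmaselect_schema_error")
  }
  gaps <- diff(obj$time_s)
  if (any(gaps <= 0)) {
    stop_gmaselect("frame timestamps must be strictly increasing",
                   "gmaselect_sampling_error")
  }
  expected <- 1 / obj$sample_rate_hz
  if (any(abs(gaps - expected) > 1e-6)) {
    stop_gmaselect(
      sprintf("non-uniform sampling: gaps deviate from 1/%g Hz by more than 1e-6 s",
              obj$sample_rate_hz),
      "gmaselect_sampling_error"
    )
  }
  invisible(obj)
}

#' Number of frames in a pose series
#' @param series A `pose_series`.
#' @return Integer frame count.
#' @export
n_frames <- function(series) length(series$time_s)

#' Extract one frame of a pose series
#'
#' @param series A `pose_series`.
#' @param i Frame index (1-based).
#' @return A `pose_frame`: list with `time_s` and length-17 vectors `x`,
#'   `y`, `confidence`.
#' @export
pose_frame <- function(series, i) {
  stopifnot(i >= 1, i <= n_frames(series))
  structure(
    list(
      time_s = series$time_s[i],
      x = series$x[i, ], y = series$y[i, ],
      confidence = series$confidence[i, ]
    ),
    class = "pose_frame"
  )
}

#' Decimate a pose series to a lower sampling rate
#'
#' Keeps every (rate/target)-th frame starting from the first, preserving
#' timestamps — the standard way to bring a 25 or 30 Hz pose stream down to
#' the 1 Hz rate the sequence selector operates at. Only integer decimation
#' is supported; interpolating upsampling is out of scope.
#'
#' @param series A `pose_series`.
#' @param target_hz Target rate; must divide `series$sample_rate_hz` to
#'   within 1e-9 of an integer ratio.
#' @return A `pose_series` at `target_hz`.
#' @export
#' @examples
#' ps <- pose_series("v", time_s = seq(0, 8.9, by = 0.1),
#'                   x = matrix(0, 90, 17), y = matrix(0, 90, 17),
#'                   confidence = matrix(1, 90, 17))
#' n_frames(resample(ps, 1))  # 9 frames, one per second
resample <- function(series, target_hz) {
  stopifnot(inherits(series, "pose_series"), is_scalar_number(target_hz),
            target_hz > 0)
  if (target_hz > series$sample_rate_hz) {
    stop_gmaselect("upsampling is not supported (target rate above series rate)",
                   "gmaselect_resampling_error")
  }
  ratio <- series$sample_rate_hz / target_hz
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop_gmaselect(
      sprintf("decimation ratio %g is not an integer", ratio),
      "gmaselect_resampling_error"
    )
  }
  keep <- seq(1L, n_frames(series), by = as.integer(round(ratio)))
  pose_series(
    video_id = series$video_id,
    time_s = series$time_s[keep],
    x = series$x[keep, , drop = FALSE],
    y = series$y[keep, , drop = FALSE],
    confidence = series$confidence[keep, , drop = FALSE],
    sample_rate_hz = target_hz,
    frame_width_px = series$frame_width_px,
    frame_height_px = series$frame_height_px
  )
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf(
    "<pose_series> video '%s': %d frames x 17 keypoints at %g Hz (%.1f s)\n",
    x$video_id, n_frames(x), x$sample_rate_hz,
    x$time_s[length(x$time_s)] - x$time_s[1]
  ))
  if (!is.null(x$frame_width_px)) {
    cat(sprintf("  frame: %d x %d px\n", x$frame_width_px, x$frame_height_px))
  }
  invisible(x)
}

#' @export
summary.pose_series <- function(object, ...) {
  cat(sprintf("Pose series '%s'\n", object$video_id))
  cat(sprintf("  frames      : %d at %g Hz\n", n_frames(object),
              object$sample_rate_hz))
  cat(sprintf("  time span   : [%.3f, %.3f] s\n", object$time_s[1],
              object$time_s[length(object$time_s)]))
  cat(sprintf("  x range     : [%.1f, %.1f] px\n", min(object$x), max(object$x)))
  cat(sprintf("  y range     : [%.1f, %.1f] px\n", min(object$y), max(object$y)))
  cat(sprintf("  confidence  : mean %.3f, min %.3f\n",
              mean(object$confidence), min(object$confidence)))
  invisible(object)
}
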