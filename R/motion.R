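#' Confidence policy for motion computation
#'
#' The motion quantity is, by definition, the plain sum of per-keypoint
#' Euclidean displacements between consecutive poses, with no confidence
#' term. Real pose estimators, however, emit low-confidence garbage for
#' occluded landmarks, so two opt-in robustness modes are provided:
#'
#' * `include_all` (default): every keypoint contributes — the literal
#'   definition.
#' * `drop_keypoint`: a keypoint contributes only if its confidence is at
#'   least `threshold` in **both** frames of the pair.
#' * `normalize`: as `drop_keypoint`, but the sum is rescaled by
#'   17 / (keypoints retained) so values stay comparable across frames with
#'   different numbers of retained keypoints; a pair retaining no keypoints
#'   scores 0 by convention.
#'
#' @param threshold Confidence threshold in \[0, 1\]; default 0.
#' @param mode One of `"include_all"`, `"drop_keypoint"`, `"normalize"`.
#' @return An object of class `confidence_policy`.
#' @export
confidence_policy <- function(threshold = 0,
                              mode = c("include_all", "drop_keypoint",
                                       "normalize")) {
  mode <- match.arg(mode)
  stopifnot(is_scalar_number(threshold), threshold >= 0, threshold <= 1)
  structure(list(threshold = threshold, mode = mode),
            class = "confidence_policy")
}

#' Displacement between two poses
#'
#' Sum of Euclidean distances between respective keypoints of two poses —
#' one sample of the motion-quantity series. Under the default policy this
#' is exactly `sum_k ||b_k - a_k||` over all 17 keypoints, in pixels.
#'
#' @param a,b `pose_frame` objects (see [pose_frame()]), or any lists with
#'   length-17 numeric `x`, `y` and `confidence` components.
#' @param policy A [confidence_policy()].
#' @return Non-negative displacement in pixels.
#' @export
#' @examples
#' f1 <- list(x = rep(0, 17), y = rep(0, 17), confidence = rep(1, 17))
#' f2 <- f1; f2$x[1] <- 3; f2$y[1] <- 4
#' frame_displacement(f1, f2)  # one 3-4-5 move: 5
frame_displacement <- function(a, b, policy = confidence_policy()) {
  stopifnot(length(a$x) == N_KEYPOINTS, length(b$x) == N_KEYPOINTS)
  d <- sqrt((b$x - a$x)^2 + (b$y - a$y)^2)
  if (policy$mode == "include_all") return(sum(d))
  keep <- a$confidence >= policy$threshold & b$confidence >= policy$threshold
  n_keep <- sum(keep)
  if (policy$mode == "drop_keypoint") return(sum(d[keep]))
  if (n_keep == 0L) return(0)
  sum(d[keep]) * N_KEYPOINTS / n_keep
}

#' Motion-quantity time series
#'
#' Computes the scalar motion quantity for each pair of consecutive poses:
#' the sum of Euclidean distances between respective keypoints, in pixels.
#' A series of F frames yields F - 1 values; value i is attached to the
#' timestamp of its leading frame. This series is the input to the
#' sequence selector ([select_top_k()]).
#'
#' @param series A `pose_series` with at least 2 frames.
#' @param policy A [confidence_policy()]; the default reproduces the plain
#'   all-keypoint sum.
#' @return An object of class `motion_series`: list with `video_id`,
#'   `values` (non-negative pixels), `time_s` (leading-frame timestamps),
#'   `sample_rate_hz` and `t0_s`.
#' @export
#' @examples
#' ps <- pose_series("v", 0:2,
#'                   x = matrix(c(0, 1, 1), 3, 17), y = matrix(0, 3, 17),
#'                   confidence = matrix(1, 3, 17))
#' motion_series(ps)$values  # 17 unit moves, then none: 17 0
motion_series <- function(series, policy = confidence_policy()) {
  stopifnot(inherits(series, "pose_series"))
  n <- n_frames(series)
  if (n < 2L) {
    stop_gmaselect("motion computation needs at least 2 frames",
                   "gmaselect_insufficient_data_error")
  }
  lead <- seq_len(n - 1L)
  dx <- series$x[lead + 1L, , drop = FALSE] - series$x[lead, , drop = FALSE]
  dy <- series$y[lead + 1L, , drop = FALSE] - series$y[lead, , drop = FALSE]
  d <- sqrt(dx^2 + dy^2)
  if (policy$mode == "include_all") {
    values <- rowSums(d)
  } else {
    keep <- series$confidence[lead, , drop = FALSE] >= policy$threshold &
      series$confidence[lead + 1L, , drop = FALSE] >= policy$threshold
    values <- rowSums(d * keep)
    if (policy$mode == "normalize") {
      n_keep <- rowSums(keep)
      values <- ifelse(n_keep == 0L, 0, values * N_KEYPOINTS / n_keep)
    }
  }
  structure(
    list(
      video_id = series$video_id,
      values = as.numeric(values),
      time_s = series$time_s[lead],
      sample_rate_hz = series$sample_rate_hz,
      t0_s = series$time_s[1]
    ),
    class = "motion_series"
  )
}

#' @export
print.motion_series <- function(x, ...) {
  cat(sprintf(
    "<motion_series> video '%s': %d values at %g Hz, total %.1f px, peak %.1f px\n",
    x$video_id, length(x$values), x$sample_rate_hz, sum(x$values),
    max(x$values)
  ))
  invisible(x)
}

#' Plot a motion-quantity series
#'
#' Line plot of motion quantity over time; optionally shades selected
#' intervals from a [select_top_k()] result.
#'
#' @param x A `motion_series`.
#' @param selection Optional `selection_result` whose intervals are shaded.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.motion_series <- function(x, selection = NULL, ...) {
  plot(x$time_s, x$values, type = "l", xlab = "time (s)",
       ylab = "motion quantity (px)",
       main = sprintf("Motion quantity: %s", x$video_id), ...)
  if (!is.null(selection)) {
    for (i in seq_len(nrow(selection$intervals))) {
      rect(selection$intervals$start_s[i], 0, selection$intervals$end_s[i],
           max(x$values), col = adjustcolor("steelblue", 0.25), border = NA)
    }
  }
  invisible(x)
}

#' Write / read a motion series as CSV
#'
#' CSV dialect: header `video_id,time_s,motion_quantity`, one row per
#' motion value, timestamp of the leading frame.
#'
#' @param motion A `motion_series`.
#' @param path CSV path.
#' @return `path` (write) or a `motion_series` (read).
#' @export
write_motion_csv <- function(motion, path) {
  df <- data.frame(video_id = motion$video_id,
                   time_s = motion$time_s,
                   motion_quantity = motion$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_csv
#' @export
read_motion_csv <- function(path) {
  if (!file.exists(path)) {
    stop_gmaselect(sprintf("file not found: %s", path), "gmaselect_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("video_id", "time_s", "motion_quantity")
  if (!identical(names(df), want)) {
    stop_gmaselect(sprintf("bad motion CSV header in %s", path),
                   "gmaselect_parse_error")
  }
  if (nrow(df) < 1L) {
    stop_gmaselect(sprintf("empty motion series in %s", path),
                   "gmaselect_insufficient_data_error")
  }
  rate <- if (nrow(df) >= 2L) 1 / stats::median(diff(df$time_s)) else 1
  structure(
    list(video_id = as.character(df$video_id[1]),
         values = as.numeric(df$motion_quantity),
         time_s = as.numeric(df$time_s),
         sample_rate_hz = rate,
         t0_s = as.numeric(df$time_s[1])),
    class = "motion_series"
  )
}
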