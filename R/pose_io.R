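# File formats exchanged with upstream pose estimators and human raters.
#
# Keypoint CSV: header video_id,time_s,kp_index,kp_name,x,y,confidence; one
#   row per keypoint per frame, kp_index 0-16 in COCO-17 order; UTF-8, '.'
#   decimal separator.
# COCO-style keypoint JSON: a top-level array of per-frame objects, each with
#   video_id, time_s and a flat 51-value keypoints array ordered
#   (x, y, confidence) x 17.
# Annotation CSV: header rater_id,video_id,start_s,end_s; half-open
#   [start_s, end_s) interval semantics.

POSE_CSV_HEADER <- c("video_id", "time_s", "kp_index", "kp_name",
                     "x", "y", "confidence")

#' Read a keypoint table into a pose series
#'
#' Parses the per-frame 17-keypoint output of a 2D pose estimator from either
#' the keypoint CSV dialect or COCO-style keypoint JSON (see Details) into a
#' validated [pose_series()]. Frames out of time order are rejected, never
#' silently sorted, and a file can only ever yield a series satisfying all
#' pose-series invariants.
#'
#' @details CSV columns are `video_id,time_s,kp_index,kp_name,x,y,confidence`
#'   with one row per keypoint per frame and `kp_index` running 0-16 in
#'   COCO-17 order within each frame. The JSON dialect is a top-level array
#'   of frame objects, each carrying `video_id`, `time_s` and a flat
#'   51-value `keypoints` array ordered (x, y, confidence) per keypoint.
#'
#' @param path Path to the file.
#' @param format One of `"csv"` (default) or `"coco_json"`.
#' @return A `pose_series`.
#' @export
read_pose_table <- function(path, format = c("csv", "coco_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_gmaselect(sprintf("file not found: %s", path), "gmaselect_io_error")
  }
  switch(format,
    csv = read_pose_csv(path),
    coco_json = read_pose_coco_json(path)
  )
}

read_pose_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (!identical(names(raw), POSE_CSV_HEADER)) {
    stop_gmaselect(
      sprintf("bad keypoint CSV header in %s: expected %s", path,
              paste(POSE_CSV_HEADER, collapse = ",")),
      "gmaselect_parse_error"
    )
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | raw[[col]] == "")
    if (length(bad)) {
      stop_gmaselect(
        sprintf("malformed value '%s' in column '%s' at line %d of %s",
                raw[[col]][bad[1]], col, bad[1] + 1L, path),
        "gmaselect_parse_error"
      )
    }
    v
  }
  time_s <- num("time_s")
  kp_index <- num("kp_index")
  x <- num("x")
  y <- num("y")
  conf <- num("confidence")

  n_rows <- nrow(raw)
  if (n_rows == 0L) {
    stop_gmaselect(sprintf("empty keypoint table: %s", path),
                   "gmaselect_schema_error")
  }
  # Frames are contiguous row blocks sharing a timestamp; each block must be
  # exactly the 17 keypoints, indexed 0..16 in order.
  frame_id <- cumsum(c(TRUE, diff(time_s) != 0))
  counts <- tabulate(frame_id)
  if (any(counts != N_KEYPOINTS)) {
    bad <- which(counts != N_KEYPOINTS)[1]
    stop_gmaselect(
      sprintf("frame %d of %s has %d keypoints, expected 17",
              bad, path, counts[bad]),
      "gmaselect_schema_error"
    )
  }
  expected_idx <- rep(0:(N_KEYPOINTS - 1L), times = max(frame_id))
  if (!all(kp_index == expected_idx)) {
    bad <- which(kp_index != expected_idx)[1]
    stop_gmaselect(
      sprintf("kp_index out of COCO-17 order at line %d of %s", bad + 1L, path),
      "gmaselect_schema_error"
    )
  }
  ft <- time_s[seq(1L, n_rows, by = N_KEYPOINTS)]
  if (any(diff(ft) < 0)) {
    stop_gmaselect(
      sprintf("frames out of time order in %s (not sorted automatically)", path),
      "gmaselect_sampling_error"
    )
  }
  shape <- function(v) matrix(v, ncol = N_KEYPOINTS, byrow = TRUE)
  pose_series(
    video_id = raw$video_id[1],
    time_s = ft,
    x = shape(x), y = shape(y), confidence = shape(conf)
  )
}

read_pose_coco_json <- function(path) {
  frames <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    error = function(e) {
      stop_gmaselect(sprintf("malformed JSON in %s: %s", path,
                             conditionMessage(e)),
                     "gmaselect_parse_error")
    }
  )
  if (length(frames) == 0L) {
    stop_gmaselect(sprintf("no frames in %s", path), "gmaselect_schema_error")
  }
  kps <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    kp <- unlist(fr$keypoints)
    if (length(kp) != 3L * N_KEYPOINTS || !is.numeric(kp)) {
      stop_gmaselect(
        sprintf("frame %d of %s: keypoints must be a flat numeric array of 51 values",
                i, path),
        "gmaselect_schema_error"
      )
    }
    if (is.null(fr$time_s) || !is.numeric(fr$time_s)) {
      stop_gmaselect(sprintf("frame %d of %s: missing numeric time_s", i, path),
                     "gmaselect_parse_error")
    }
    kp
  })
  time_s <- vapply(frames, function(fr) as.numeric(fr$time_s), numeric(1))
  if (any(diff(time_s) < 0)) {
    stop_gmaselect(
      sprintf("frames out of time order in %s (not sorted automatically)", path),
      "gmaselect_sampling_error"
    )
  }
  m <- do.call(rbind, kps)
  idx <- seq(1L, 3L * N_KEYPOINTS, by = 3L)
  pose_series(
    video_id = as.character(frames[[1]]$video_id %||% "unknown"),
    time_s = time_s,
    x = m[, idx, drop = FALSE],
    y = m[, idx + 1L, drop = FALSE],
    confidence = m[, idx + 2L, drop = FALSE]
  )
}

#' Write a pose series to a keypoint table
#'
#' Inverse of [read_pose_table()]: the written file reads back to an
#' identical series, with coordinates and confidences preserved to 6 decimal
#' places (CSV) or full double precision (JSON).
#'
#' @param series A valid `pose_series`.
#' @param path Output path.
#' @param format One of `"csv"` or `"coco_json"`.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(series, path, format = c("csv", "coco_json")) {
  format <- match.arg(format)
  validate_pose_series(series)
  if (format == "csv") {
    n <- n_frames(series)
    df <- data.frame(
      video_id = rep(series$video_id, n * N_KEYPOINTS),
      time_s = sprintf("%.6f", rep(series$time_s, each = N_KEYPOINTS)),
      kp_index = rep(0:(N_KEYPOINTS - 1L), times = n),
      kp_name = rep(coco17_keypoints(), times = n),
      x = sprintf("%.6f", as.vector(t(series$x))),
      y = sprintf("%.6f", as.vector(t(series$y))),
      confidence = sprintf("%.6f", as.vector(t(series$confidence)))
    )
    ok <- tryCatch(
      {
        utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) {
      stop_gmaselect(sprintf("cannot write %s", path), "gmaselect_io_error")
    }
  } else {
    frames <- lapply(seq_len(n_frames(series)), function(i) {
      list(
        video_id = series$video_id,
        time_s = series$time_s[i],
        keypoints = as.vector(rbind(series$x[i, ], series$y[i, ],
                                    series$confidence[i, ]))
      )
    })
    tryCatch(
      jsonlite::write_json(frames, path, auto_unbox = TRUE, digits = NA),
      error = function(e) {
        stop_gmaselect(sprintf("cannot write %s", path), "gmaselect_io_error")
      }
    )
  }
  invisible(path)
}

#' Construct an expert annotation
#'
#' One rater's selected time intervals for one video, in the order the rater
#' listed them. Intervals are half-open `[start_s, end_s)` seconds.
#'
#' @param rater_id,video_id Identifier strings.
#' @param intervals Data frame with columns `start_s`, `end_s`.
#' @return An object of class `expert_annotation`.
#' @export
expert_annotation <- function(rater_id, video_id, intervals) {
  intervals <- as.data.frame(intervals)[, c("start_s", "end_s")]
  if (nrow(intervals) > 0 && any(intervals$end_s <= intervals$start_s)) {
    stop_gmaselect("annotation intervals must satisfy end_s > start_s",
                   "gmaselect_validation_error")
  }
  structure(
    list(rater_id = as.character(rater_id),
         video_id = as.character(video_id),
         intervals = intervals),
    class = "expert_annotation"
  )
}

#' @export
print.expert_annotation <- function(x, ...) {
  cat(sprintf("<expert_annotation> rater '%s', video '%s': %d interval(s)\n",
              x$rater_id, x$video_id, nrow(x$intervals)))
  if (nrow(x$intervals)) print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Read expert annotations
#'
#' Reads the annotation CSV dialect (`rater_id,video_id,start_s,end_s`,
#' half-open seconds) into one [expert_annotation()] per (rater, video) pair,
#' intervals kept in file order.
#'
#' @param path Path to an annotation CSV.
#' @return A list of `expert_annotation` objects (empty list for an empty
#'   file).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop_gmaselect(sprintf("file not found: %s", path), "gmaselect_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  want <- c("rater_id", "video_id", "start_s", "end_s")
  if (!identical(names(df), want)) {
    stop_gmaselect(
      sprintf("bad annotation header in %s: expected %s", path,
              paste(want, collapse = ",")),
      "gmaselect_parse_error"
    )
  }
  if (nrow(df) == 0L) return(list())
  start_s <- suppressWarnings(as.numeric(df$start_s))
  end_s <- suppressWarnings(as.numeric(df$end_s))
  bad <- which(is.na(start_s) | is.na(end_s))
  if (length(bad)) {
    stop_gmaselect(
      sprintf("malformed interval at line %d of %s", bad[1] + 1L, path),
      "gmaselect_parse_error"
    )
  }
  if (any(end_s <= start_s)) {
    i <- which(end_s <= start_s)[1]
    stop_gmaselect(
      sprintf("interval with end <= start at line %d of %s", i + 1L, path),
      "gmaselect_validation_error"
    )
  }
  key <- paste(df$rater_id, df$video_id, start_s, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop_gmaselect(
      sprintf("duplicate (rater, video, start) row at line %d of %s",
              i + 1L, path),
      "gmaselect_validation_error"
    )
  }
  grp <- paste(df$rater_id, df$video_id, sep = "\r")
  out <- lapply(unique(grp), function(g) {
    rows <- grp == g
    expert_annotation(
      rater_id = df$rater_id[rows][1],
      video_id = df$video_id[rows][1],
      intervals = data.frame(start_s = start_s[rows], end_s = end_s[rows])
    )
  })
  out
}

#' Write expert annotations
#'
#' @param annotations A list of `expert_annotation` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    if (nrow(a$intervals) == 0L) return(NULL)
    data.frame(rater_id = a$rater_id, video_id = a$video_id,
               start_s = a$intervals$start_s, end_s = a$intervals$end_s)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(rater_id = character(), video_id = character(),
               start_s = numeric(), end_s = numeric())
  )))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
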