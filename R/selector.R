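#' A half-open time interval
#'
#' The unit of both automatic selection and expert annotation: a span
#' `[start_s, end_s)` in seconds from video start.
#'
#' @param start_s Start, seconds, >= 0.
#' @param end_s End, seconds, strictly greater than `start_s`.
#' @return An object of class `time_interval`.
#' @export
time_interval <- function(start_s, end_s) {
  stopifnot(is_scalar_number(start_s), is_scalar_number(end_s), start_s >= 0)
  if (end_s <= start_s) {
    stop_gmaselect("time interval must have end_s > start_s",
                   "gmaselect_validation_error")
  }
  structure(list(start_s = start_s, end_s = end_s), class = "time_interval")
}

#' @export
print.time_interval <- function(x, ...) {
  cat(sprintf("[%g, %g) s\n", x$start_s, x$end_s))
  invisible(x)
}

interval_length <- function(x) x$end_s - x$start_s

# Window length in samples; warns when the requested duration is not a whole
# number of samples (the selection then uses the rounded duration).
window_samples <- function(window_s, sample_rate_hz) {
  w_exact <- window_s * sample_rate_hz
  w <- as.integer(round(w_exact))
  if (abs(w_exact - w) > 1e-6) {
    warning(sprintf(
      "window of %g s is not a whole number of samples at %g Hz; using %d samples (%.3f s)",
      window_s, sample_rate_hz, w, w / sample_rate_hz
    ), call. = FALSE)
  }
  w
}

#' Summing-window scores over a motion series
#'
#' For a window of W samples (W = round(`window_s` x sampling rate)),
#' computes the total motion quantity `G(j) = sum(values[j .. j+W-1])` for
#' every admissible 0-based start index j — the objective the sequence
#' selector maximises. Computed in O(n) with a running sum.
#'
#' @param motion A `motion_series`.
#' @param window_s Window duration in seconds (60 by default downstream:
#'   the standard one-minute GMA sequence).
#' @return Data frame with columns `start_index` (0-based), `start_s` and
#'   `score` (pixel-samples).
#' @export
window_scores <- function(motion, window_s) {
  stopifnot(inherits(motion, "motion_series"), is_scalar_number(window_s),
            window_s > 0)
  w <- window_samples(window_s, motion$sample_rate_hz)
  n <- length(motion$values)
  if (w < 1L || w > n) {
    stop_gmaselect(
      sprintf("window of %d samples does not fit a motion series of length %d",
              w, n),
      "gmaselect_window_error"
    )
  }
  cs <- c(0, cumsum(motion$values))
  j <- 0:(n - w)
  data.frame(
    start_index = j,
    start_s = motion$t0_s + j / motion$sample_rate_hz,
    score = cs[j + w + 1L] - cs[j + 1L]
  )
}

#' Select the single highest-motion sequence
#'
#' Returns the fixed-duration interval maximising the summing-window score;
#' ties go to the smallest start index. This is the selector's core rule;
#' [select_top_k()] generalises it to several sequences.
#'
#' @inheritParams window_scores
#' @return A [time_interval()] with attributes `score` and `start_index`.
#' @export
select_best <- function(motion, window_s) {
  sc <- window_scores(motion, window_s)
  i <- which.max(sc$score)  # first maximum = minimum index
  w <- window_samples(window_s, motion$sample_rate_hz)
  out <- time_interval(sc$start_s[i], sc$start_s[i] + w / motion$sample_rate_hz)
  attr(out, "score") <- sc$score[i]
  attr(out, "start_index") <- sc$start_index[i]
  out
}

#' Select the K highest-motion sequences
#'
#' Generalises [select_best()] to `k` sequences. In `disjoint` mode
#' (default) selection is greedy: take the best window, discard every window
#' overlapping it in sample-index space, repeat — so returned intervals
#' never overlap, matching how distinct GMA sequences are reviewed. In
#' `free` mode the k largest scores are taken regardless of overlap (useful
#' for sensitivity analysis). All ties resolve to the smallest start index.
#' If fewer than `k` disjoint windows exist, the result is truncated and a
#' warning emitted.
#'
#' @inheritParams window_scores
#' @param k Number of sequences requested (>= 1).
#' @param overlap `"disjoint"` or `"free"`.
#' @return An object of class `selection_result`: `video_id`, `intervals`
#'   (data frame `start_s`, `end_s`, ordered by descending score, ties by
#'   ascending start), `scores`, `window_s` (actual, after rounding to whole
#'   samples), `k_requested`, `k_returned`.
#' @export
#' @examples
#' m <- structure(list(video_id = "v", values = c(0, 5, 0, 4, 0),
#'                     time_s = 0:4, sample_rate_hz = 1, t0_s = 0),
#'                class = "motion_series")
#' select_top_k(m, window_s = 1, k = 2)
select_top_k <- function(motion, window_s, k,
                         overlap = c("disjoint", "free")) {
  overlap <- match.arg(overlap)
  stopifnot(is_scalar_number(k), k >= 1, k == round(k))
  k <- as.integer(k)
  sc <- window_scores(motion, window_s)
  w <- window_samples(window_s, motion$sample_rate_hz)
  dur <- w / motion$sample_rate_hz

  if (overlap == "free") {
    ord <- order(-sc$score, sc$start_index)
    pick <- ord[seq_len(min(k, length(ord)))]
  } else {
    pick <- integer(0)
    alive <- rep(TRUE, nrow(sc))
    while (length(pick) < k && any(alive)) {
      scores_alive <- ifelse(alive, sc$score, -Inf)
      i <- which.max(scores_alive)
      pick <- c(pick, i)
      alive[abs(sc$start_index - sc$start_index[i]) < w] <- FALSE
    }
  }
  if (length(pick) < k) {
    warning(sprintf("video '%s': only %d of %d requested sequences available",
                    motion$video_id, length(pick), k), call. = FALSE)
  }
  structure(
    list(
      video_id = motion$video_id,
      intervals = data.frame(start_s = sc$start_s[pick],
                             end_s = sc$start_s[pick] + dur),
      scores = sc$score[pick],
      window_s = dur,
      k_requested = k,
      k_returned = length(pick)
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> video '%s': %d/%d sequence(s) of %g s\n",
              x$video_id, x$k_returned, x$k_requested, x$window_s))
  if (x$k_returned) {
    print(data.frame(rank = seq_len(x$k_returned), x$intervals,
                     score = x$scores),
          row.names = FALSE)
  }
  invisible(x)
}

#' Write / read selection results as CSV
#'
#' CSV dialect: header `video_id,rank,start_s,end_s,score`, one row per
#' selected sequence, ranks within each video.
#'
#' @param selections A `selection_result` or list of them.
#' @param path CSV path.
#' @return `path` (write) or a named list of `selection_result` (read).
#' @export
write_selections <- function(selections, path) {
  if (inherits(selections, "selection_result")) selections <- list(selections)
  rows <- lapply(selections, function(s) {
    if (s$k_returned == 0L) return(NULL)
    data.frame(video_id = s$video_id, rank = seq_len(s$k_returned),
               start_s = s$intervals$start_s, end_s = s$intervals$end_s,
               score = s$scores)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_selections
#' @export
read_selections <- function(path) {
  if (!file.exists(path)) {
    stop_gmaselect(sprintf("file not found: %s", path), "gmaselect_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("video_id", "rank", "start_s", "end_s", "score")
  if (!identical(names(df), want)) {
    stop_gmaselect(sprintf("bad selection CSV header in %s", path),
                   "gmaselect_parse_error")
  }
  out <- lapply(split(df, df$video_id), function(d) {
    d <- d[order(d$rank), ]
    structure(
      list(video_id = as.character(d$video_id[1]),
           intervals = data.frame(start_s = d$start_s, end_s = d$end_s),
           scores = d$score,
           window_s = d$end_s[1] - d$start_s[1],
           k_requested = nrow(d),
           k_returned = nrow(d)),
      class = "selection_result"
    )
  })
  out[order(names(out))]
}
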