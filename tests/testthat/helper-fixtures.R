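# Fixture builders and independent oracles. The oracles re-derive every
# quantity by direct enumeration (double loops, literal formulas) and never
# share code with the package internals they check.

random_pose_series <- function(n_frames = 20, rate = 1, seed = 1,
                               video_id = "rv", width = 1280, height = 720) {
  set.seed(seed)
  pose_series(
    video_id = video_id,
    time_s = (seq_len(n_frames) - 1) / rate,
    x = matrix(runif(n_frames * 17, 0, width), n_frames, 17),
    y = matrix(runif(n_frames * 17, 0, height), n_frames, 17),
    confidence = matrix(runif(n_frames * 17), n_frames, 17),
    sample_rate_hz = rate
  )
}

random_motion <- function(n, seed = 1, rate = 1, video_id = "rm") {
  set.seed(seed)
  structure(
    list(video_id = video_id, values = runif(n, 0, 10),
         time_s = (seq_len(n) - 1) / rate, sample_rate_hz = rate, t0_s = 0),
    class = "motion_series"
  )
}

motion_from_values <- function(values, rate = 1, t0 = 0, video_id = "mv") {
  structure(
    list(video_id = video_id, values = values,
         time_s = t0 + (seq_along(values) - 1) / rate,
         sample_rate_hz = rate, t0_s = t0),
    class = "motion_series"
  )
}

# O(n*W) brute-force window sums by direct summation, start indices 0-based.
oracle_window_scores <- function(values, w) {
  starts <- 0:(length(values) - w)
  vapply(starts, function(j) sum(values[(j + 1):(j + w)]), numeric(1))
}

oracle_select_best <- function(values, w) {
  sc <- oracle_window_scores(values, w)
  which.max(sc) - 1L  # first max = minimum start index
}

# Greedy disjoint top-k on brute-force scores with the min-index tie rule.
oracle_greedy_disjoint <- function(values, w, k) {
  sc <- oracle_window_scores(values, w)
  starts <- 0:(length(values) - w)
  picked <- integer(0)
  alive <- rep(TRUE, length(sc))
  while (length(picked) < k && any(alive)) {
    best <- -Inf
    best_i <- NA_integer_
    for (i in seq_along(sc)) {
      if (alive[i] && sc[i] > best) {
        best <- sc[i]
        best_i <- i
      }
    }
    picked <- c(picked, starts[best_i])
    alive[abs(starts - starts[best_i]) < w] <- FALSE
  }
  picked
}

make_annotation <- function(rater, video, starts, dur = 60) {
  expert_annotation(rater, video,
                    data.frame(start_s = starts, end_s = starts + dur))
}

make_selection <- function(video, starts, dur = 60, scores = NULL) {
  structure(
    list(video_id = video,
         intervals = data.frame(start_s = starts, end_s = starts + dur),
         scores = scores %||% rev(seq_along(starts)),
         window_s = dur, k_requested = length(starts),
         k_returned = length(starts)),
    class = "selection_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Literal re-derivations of the agreement formulas.
oracle_intersection <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

oracle_dice <- function(s1, e1, s2, e2) {
  2 * oracle_intersection(s1, e1, s2, e2) / ((e1 - s1) + (e2 - s2))
}

# MDS of interval (s, e) against a list of annotations: per rater, match by
# max intersection (ties -> lowest index), then max dice over raters.
oracle_mds <- function(s, e, anns) {
  best <- -Inf
  for (a in anns) {
    iv <- a$intervals
    inter <- numeric(nrow(iv))
    for (j in seq_len(nrow(iv))) {
      inter[j] <- oracle_intersection(s, e, iv$start_s[j], iv$end_s[j])
    }
    cj <- which.max(inter)
    d <- oracle_dice(s, e, iv$start_s[cj], iv$end_s[cj])
    if (d > best) best <- d
  }
  best
}

oracle_precision <- function(selections, anns, tau) {
  hits <- 0L
  total <- 0L
  for (sel in selections) {
    mine <- Filter(function(a) a$video_id == sel$video_id, anns)
    for (i in seq_len(nrow(sel$intervals))) {
      total <- total + 1L
      m <- oracle_mds(sel$intervals$start_s[i], sel$intervals$end_s[i], mine)
      if (m > tau) hits <- hits + 1L
    }
  }
  hits / total
}

# Random annotation panels over shared videos for pipeline-oracle tests.
random_annotation_panel <- function(n_videos, n_raters, ns, seed,
                                    video_len = 600, dur = 60) {
  set.seed(seed)
  anns <- list()
  for (v in seq_len(n_videos)) {
    for (r in seq_len(n_raters)) {
      starts <- runif(ns, 0, video_len - dur)
      anns[[length(anns) + 1L]] <- make_annotation(
        sprintf("r%d", r), sprintf("v%d", v), starts, dur
      )
    }
  }
  anns
}
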