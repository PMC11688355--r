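# Agreement machinery between automatic selections and expert annotations:
# interval intersection, dice similarity, per-sequence maximum dice
# similarity (MDS) over raters, and precision-versus-threshold curves,
# including leave-one-expert-out and inter-rater variants.

as_interval <- function(x) {
  if (inherits(x, "time_interval")) return(x)
  if (is.list(x) && !is.null(x$start_s) && !is.null(x$end_s)) {
    return(time_interval(x$start_s, x$end_s))
  }
  stop_gmaselect("not a time interval", "gmaselect_validation_error")
}

#' Overlap of two time intervals
#'
#' Length, in seconds, of the overlap between two half-open intervals:
#' `max(0, min(ends) - max(starts))`. Symmetric, and never larger than the
#' shorter interval.
#'
#' @param x,y [time_interval()] objects (or lists with `start_s`, `end_s`).
#' @return Overlap in seconds, >= 0.
#' @export
#' @examples
#' interval_intersection(time_interval(0, 60), time_interval(30, 90))  # 30
interval_intersection <- function(x, y) {
  x <- as_interval(x); y <- as_interval(y)
  max(0, min(x$end_s, y$end_s) - max(x$start_s, y$start_s))
}

#' Dice similarity of two time intervals
#'
#' `2 * overlap / (|x| + |y|)`: 1 for identical intervals, 0 for disjoint
#' ones, and in between proportional to the overlap relative to the mean
#' duration. Handles unequal durations.
#'
#' @inheritParams interval_intersection
#' @return Dice similarity in \[0, 1\].
#' @export
#' @examples
#' dice_similarity(time_interval(0, 60), time_interval(30, 90))  # 0.5
dice_similarity <- function(x, y) {
  x <- as_interval(x); y <- as_interval(y)
  2 * interval_intersection(x, y) / (interval_length(x) + interval_length(y))
}

#' Match a selected sequence to one expert's annotations
#'
#' Finds, among one rater's intervals, the one with the largest overlap with
#' the software-selected interval `x` (ties resolve to the lowest interval
#' index, including the all-zero-overlap case). Matching is independent per
#' software sequence: the same expert interval may be matched by several
#' software sequences.
#'
#' @param x A [time_interval()].
#' @param expert An [expert_annotation()] with at least one interval.
#' @return A `matched_pair`: list with `software_interval`,
#'   `expert_interval`, `expert_index` (1-based), `intersection_s`, `dice`.
#' @export
match_expert_sequence <- function(x, expert) {
  x <- as_interval(x)
  stopifnot(inherits(expert, "expert_annotation"))
  iv <- expert$intervals
  if (nrow(iv) == 0L) {
    stop_gmaselect(
      sprintf("rater '%s' has no intervals for video '%s'",
              expert$rater_id, expert$video_id),
      "gmaselect_validation_error"
    )
  }
  inter <- vapply(seq_len(nrow(iv)), function(j) {
    interval_intersection(x, time_interval(iv$start_s[j], iv$end_s[j]))
  }, numeric(1))
  c_idx <- which.max(inter)  # first maximum = minimum index
  matched <- time_interval(iv$start_s[c_idx], iv$end_s[c_idx])
  structure(
    list(
      software_interval = x,
      expert_interval = matched,
      expert_index = c_idx,
      intersection_s = inter[c_idx],
      dice = dice_similarity(x, matched)
    ),
    class = "matched_pair"
  )
}

#' @export
print.matched_pair <- function(x, ...) {
  cat(sprintf(
    "<matched_pair> [%g, %g) ~ expert #%d [%g, %g): overlap %.2f s, dice %.3f\n",
    x$software_interval$start_s, x$software_interval$end_s, x$expert_index,
    x$expert_interval$start_s, x$expert_interval$end_s,
    x$intersection_s, x$dice
  ))
  invisible(x)
}

#' Maximum dice similarity over a group of raters
#'
#' For each rater, match `x` to that rater's best-overlapping interval, then
#' take the largest dice similarity across raters. MDS = 1 means the
#' sequence was selected essentially identically by at least one rater;
#' MDS = 0 means no rater's selection overlaps it at all.
#'
#' @param x A [time_interval()].
#' @param experts Non-empty list of [expert_annotation()] objects (one per
#'   rater, all for the same video).
#' @return MDS in \[0, 1\].
#' @export
max_dice_similarity <- function(x, experts) {
  if (length(experts) == 0L) {
    stop_gmaselect("need at least one expert annotation",
                   "gmaselect_validation_error")
  }
  max(vapply(experts, function(e) match_expert_sequence(x, e)$dice,
             numeric(1)))
}

annotations_for_video <- function(experts, video_id) {
  Filter(function(e) e$video_id == video_id, experts)
}

rater_ids <- function(experts) {
  unique(vapply(experts, function(e) e$rater_id, character(1)))
}

# Per-sequence MDS table for a set of per-video selections against a set of
# expert annotations. The denominator of precision is the number of rows.
mds_table <- function(selections, experts, warn_short = TRUE) {
  if (inherits(selections, "selection_result")) selections <- list(selections)
  rows <- lapply(selections, function(sel) {
    ex <- annotations_for_video(experts, sel$video_id)
    if (length(ex) == 0L) {
      stop_gmaselect(
        sprintf("no expert annotations for video '%s'", sel$video_id),
        "gmaselect_validation_error"
      )
    }
    if (warn_short && sel$k_returned < sel$k_requested) {
      warning(sprintf(
        "video '%s' yielded %d of %d requested sequences; precision denominator uses %d",
        sel$video_id, sel$k_returned, sel$k_requested, sel$k_returned
      ), call. = FALSE)
    }
    if (sel$k_returned == 0L) return(NULL)
    mds <- vapply(seq_len(sel$k_returned), function(i) {
      max_dice_similarity(
        time_interval(sel$intervals$start_s[i], sel$intervals$end_s[i]), ex
      )
    }, numeric(1))
    data.frame(video_id = sel$video_id, rank = seq_len(sel$k_returned),
               mds = mds)
  })
  do.call(rbind, rows)
}

#' Software-experts agreement precision
#'
#' Fraction of software-selected sequences, across all videos, whose maximum
#' dice similarity against the raters strictly exceeds the threshold `tau`.
#' The denominator is the total number of selected sequences (sequences
#' actually returned). Note the strict inequality: even perfect selections
#' score 0 at `tau = 1`.
#'
#' @param selections A `selection_result` or list of them (one per video).
#' @param experts List of [expert_annotation()] covering every selected
#'   video.
#' @param tau Threshold in \[0, 1\].
#' @return Precision in \[0, 1\].
#' @export
precision <- function(selections, experts, tau) {
  stopifnot(is_scalar_number(tau), tau >= 0, tau <= 1)
  tab <- mds_table(selections, experts)
  mean(tab$mds > tau)
}

#' Precision over a threshold grid
#'
#' Evaluates [precision()] at each threshold of a grid (default 0, 0.01,
#' ..., 1), producing the step curve used to compare automatic and expert
#' selections.
#'
#' @inheritParams precision
#' @param tau_grid Increasing thresholds in \[0, 1\].
#' @param warn_short Warn when a video returned fewer sequences than
#'   requested.
#' @return An object of class `precision_curve`: `tau`, `precision`,
#'   `n_sequences` (the denominator).
#' @export
precision_curve <- function(selections, experts,
                            tau_grid = seq(0, 1, by = 0.01),
                            warn_short = TRUE) {
  stopifnot(is.numeric(tau_grid), !is.unsorted(tau_grid),
            all(tau_grid >= 0 & tau_grid <= 1))
  tab <- mds_table(selections, experts, warn_short = warn_short)
  new_precision_curve(
    tau = tau_grid,
    precision = vapply(tau_grid, function(t) mean(tab$mds > t), numeric(1)),
    n_sequences = nrow(tab)
  )
}

new_precision_curve <- function(tau, precision, n_sequences) {
  structure(list(tau = tau, precision = precision,
                 n_sequences = n_sequences),
            class = "precision_curve")
}

#' @export
print.precision_curve <- function(x, ...) {
  at <- function(t) x$precision[which.min(abs(x$tau - t))]
  cat(sprintf(
    "<precision_curve> %d sequence(s); precision %.3f at tau=0.25, %.3f at tau=0.5, %.3f at tau=0.75\n",
    x$n_sequences %||% NA_integer_, at(0.25), at(0.5), at(0.75)
  ))
  invisible(x)
}

#' @export
plot.precision_curve <- function(x, add = FALSE, col = "black", ...) {
  if (add) {
    lines(x$tau, x$precision, type = "s", col = col, ...)
  } else {
    plot(x$tau, x$precision, type = "s", ylim = c(0, 1),
         xlab = expression(tau), ylab = "precision", col = col, ...)
  }
  invisible(x)
}

#' Precision at a threshold, read off a curve
#' @param curve A `precision_curve`.
#' @param tau Threshold; must be a grid point.
#' @return Precision value.
#' @export
precision_at <- function(curve, tau) {
  i <- which(abs(curve$tau - tau) < 1e-9)
  if (length(i) != 1L) {
    stop_gmaselect(sprintf("tau = %g is not on the curve's grid", tau),
                   "gmaselect_validation_error")
  }
  curve$precision[i]
}

#' Leave-one-expert-out precision curves
#'
#' For each rater in turn, recomputes the software-versus-experts precision
#' curve with that rater excluded from the MDS maximum. With four raters
#' this yields four comparable curves showing how much the agreement relies
#' on any single rater.
#'
#' @inheritParams precision_curve
#' @return Named list of `precision_curve`, one per excluded rater.
#' @export
leave_one_out_precision <- function(selections, experts,
                                    tau_grid = seq(0, 1, by = 0.01)) {
  ids <- rater_ids(experts)
  if (length(ids) < 2L) {
    stop_gmaselect("leave-one-out needs at least 2 raters",
                   "gmaselect_validation_error")
  }
  out <- lapply(ids, function(r) {
    rest <- Filter(function(e) e$rater_id != r, experts)
    precision_curve(selections, rest, tau_grid, warn_short = FALSE)
  })
  setNames(out, ids)
}

#' Inter-rater precision curves
#'
#' Each rater's intervals in turn play the role of the selected sequences
#' and are scored against the remaining raters, giving a human-vs-human
#' agreement baseline on the same scale as the software curves. The
#' denominator for rater e counts e's own sequences across videos.
#'
#' @param experts List of [expert_annotation()]; at least 2 raters, each
#'   annotating the same videos.
#' @param tau_grid Increasing thresholds in \[0, 1\].
#' @return Named list of `precision_curve`, one per rater.
#' @export
inter_rater_precision <- function(experts, tau_grid = seq(0, 1, by = 0.01)) {
  ids <- rater_ids(experts)
  if (length(ids) < 2L) {
    stop_gmaselect("inter-rater precision needs at least 2 raters",
                   "gmaselect_validation_error")
  }
  out <- lapply(ids, function(r) {
    mine <- Filter(function(e) e$rater_id == r, experts)
    rest <- Filter(function(e) e$rater_id != r, experts)
    pseudo <- lapply(mine, function(a) {
      structure(
        list(video_id = a$video_id, intervals = a$intervals,
             scores = rep(NA_real_, nrow(a$intervals)),
             window_s = if (nrow(a$intervals)) {
               a$intervals$end_s[1] - a$intervals$start_s[1]
             } else NA_real_,
             k_requested = nrow(a$intervals),
             k_returned = nrow(a$intervals)),
        class = "selection_result"
      )
    })
    precision_curve(pseudo, rest, tau_grid, warn_short = FALSE)
  })
  setNames(out, ids)
}

#' Average a set of precision curves
#'
#' Pointwise arithmetic mean and population standard deviation over curves
#' sharing a threshold grid — the summary used to compare the
#' software-experts agreement band against the inter-rater band.
#'
#' @param curves Non-empty list of `precision_curve` on identical grids.
#' @return List with `mean` and `sd`, both `precision_curve` objects (`sd`
#'   carries the deviations in its `precision` field).
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1L)
  tau <- curves[[1]]$tau
  for (cv in curves) {
    if (length(cv$tau) != length(tau) || any(abs(cv$tau - tau) > 1e-9)) {
      stop_gmaselect("precision curves must share the same tau grid",
                     "gmaselect_validation_error")
    }
  }
  m <- do.call(rbind, lapply(curves, function(cv) cv$precision))
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(sweep(m, 2, mu)^2))  # population sd
  list(
    mean = new_precision_curve(tau, mu, NA_integer_),
    sd = new_precision_curve(tau, sigma, NA_integer_)
  )
}

#' Full agreement evaluation
#'
#' Runs the whole agreement analysis for a set of per-video selections
#' against a panel of raters: the per-sequence MDS table, the
#' software-vs-all-experts precision curve, leave-one-expert-out curves,
#' inter-rater curves, and the mean/sd summaries of the latter two
#' families.
#'
#' @inheritParams precision_curve
#' @return An object of class `evaluation_report`.
#' @export
evaluate_selections <- function(selections, experts,
                                tau_grid = seq(0, 1, by = 0.01)) {
  if (inherits(selections, "selection_result")) selections <- list(selections)
  tab <- mds_table(selections, experts)
  sw <- precision_curve(selections, experts, tau_grid, warn_short = FALSE)
  ids <- rater_ids(experts)
  loo <- if (length(ids) >= 2L) {
    leave_one_out_precision(selections, experts, tau_grid)
  } else NULL
  ir <- if (length(ids) >= 2L) {
    inter_rater_precision(experts, tau_grid)
  } else NULL
  structure(
    list(
      per_sequence_mds = tab,
      software_vs_experts = sw,
      leave_one_out = loo,
      inter_rater = ir,
      averages = list(
        software = if (!is.null(loo)) average_curves(loo) else NULL,
        inter_rater = if (!is.null(ir)) average_curves(ir) else NULL
      ),
      meta = list(
        n_videos = length(selections),
        n_sequences = nrow(tab),
        n_experts = length(ids),
        tau_grid = tau_grid
      )
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %d video(s), %d sequence(s), %d rater(s)\n",
    x$meta$n_videos, x$meta$n_sequences, x$meta$n_experts
  ))
  cat(sprintf("  software vs all experts: precision %.3f at tau = 0.5\n",
              precision_at(x$software_vs_experts, 0.5)))
  if (!is.null(x$averages$software)) {
    cat(sprintf("  leave-one-out mean     : precision %.3f at tau = 0.5\n",
                precision_at(x$averages$software$mean, 0.5)))
  }
  if (!is.null(x$averages$inter_rater)) {
    cat(sprintf("  inter-rater mean       : precision %.3f at tau = 0.5\n",
                precision_at(x$averages$inter_rater$mean, 0.5)))
  }
  invisible(x)
}

#' @export
summary.evaluation_report <- function(object, ...) {
  print(object)
  cat("\nPer-sequence MDS:\n")
  print(object$per_sequence_mds, row.names = FALSE)
  invisible(object)
}

#' Plot an evaluation report
#'
#' Mean leave-one-out software-experts curve and mean inter-rater curve with
#' +/- 1 sd bands, on one set of axes.
#'
#' @param x An `evaluation_report` with at least 2 raters.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.evaluation_report <- function(x, ...) {
  if (is.null(x$averages$software)) {
    plot(x$software_vs_experts, ...)
    return(invisible(x))
  }
  band <- function(avg, col) {
    up <- pmin(1, avg$mean$precision + avg$sd$precision)
    lo <- pmax(0, avg$mean$precision - avg$sd$precision)
    graphics::polygon(c(avg$mean$tau, rev(avg$mean$tau)), c(up, rev(lo)),
                      col = adjustcolor(col, 0.2), border = NA)
    lines(avg$mean$tau, avg$mean$precision, type = "s", col = col, lwd = 2)
  }
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = expression(tau),
       ylab = "precision", ...)
  band(x$averages$software, "steelblue")
  band(x$averages$inter_rater, "firebrick")
  legend("bottomleft", legend = c("software vs experts (LOO mean)",
                                  "inter-rater mean"),
         col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(x)
}

#' Export an evaluation report
#'
#' `write_report_json()` writes the full report (MDS table, every curve with
#' its grid, metadata) as JSON; `write_curve_csv()` writes one curve as a
#' two-column CSV.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  curve_obj <- function(cv) {
    if (is.null(cv)) return(NULL)
    list(tau = cv$tau, precision = cv$precision,
         n_sequences = cv$n_sequences)
  }
  payload <- list(
    meta = report$meta,
    per_sequence_mds = report$per_sequence_mds,
    software_vs_experts = curve_obj(report$software_vs_experts),
    leave_one_out = lapply(report$leave_one_out, curve_obj),
    inter_rater = lapply(report$inter_rater, curve_obj),
    averages = list(
      software = lapply(report$averages$software, curve_obj),
      inter_rater = lapply(report$averages$inter_rater, curve_obj)
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @param curve A `precision_curve`.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(tau = curve$tau, precision = curve$precision),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
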