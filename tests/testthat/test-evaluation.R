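iv <- time_interval

test_that("interval intersection follows the overlap formula", {
  expect_equal(interval_intersection(iv(0, 60), iv(0, 60)), 60)
  expect_equal(interval_intersection(iv(0, 60), iv(60, 120)), 0)
  expect_equal(interval_intersection(iv(0, 60), iv(30, 90)), 30)
  # symmetry and bounds on random pairs
  set.seed(1)
  for (i in 1:50) {
    a <- sort(runif(2, 0, 600)); b <- sort(runif(2, 0, 600))
    x <- iv(a[1], a[2] + 1); y <- iv(b[1], b[2] + 1)
    expect_equal(interval_intersection(x, y), interval_intersection(y, x))
    expect_gte(interval_intersection(x, y), 0)
    expect_lte(interval_intersection(x, y),
               min(x$end_s - x$start_s, y$end_s - y$start_s))
    expect_equal(interval_intersection(x, x), x$end_s - x$start_s)
  }
})

test_that("dice similarity satisfies its axioms", {
  expect_equal(dice_similarity(iv(0, 60), iv(0, 60)), 1)
  expect_equal(dice_similarity(iv(0, 60), iv(100, 160)), 0)
  expect_equal(dice_similarity(iv(0, 60), iv(30, 90)), 0.5)
  # unequal durations are handled
  expect_equal(dice_similarity(iv(0, 60), iv(0, 30)), 2 * 30 / 90)
  set.seed(2)
  for (i in 1:100) {
    a <- sort(runif(2, 0, 500)); b <- sort(runif(2, 0, 500))
    x <- iv(a[1], a[2] + 0.5); y <- iv(b[1], b[2] + 0.5)
    d <- dice_similarity(x, y)
    expect_equal(d, dice_similarity(y, x))
    expect_true(d >= 0 && d <= 1)
    expect_equal(d == 0, interval_intersection(x, y) == 0)
    expect_equal(dice_similarity(x, x), 1)
  }
})

test_that("expert matching maximises intersection with min-index ties", {
  x <- iv(100, 160)
  ann <- make_annotation("e1", "v", c(0, 90, 400))
  m <- match_expert_sequence(x, ann)
  expect_equal(m$expert_index, 2)
  expect_equal(m$intersection_s, 50)
  expect_equal(m$dice, 2 * 50 / 120)

  # disjoint from everything: all-zero tie resolves to index 1
  far <- match_expert_sequence(iv(1000, 1060), ann)
  expect_equal(far$expert_index, 1)
  expect_equal(far$intersection_s, 0)
  expect_equal(far$dice, 0)

  # equal overlaps resolve to the lower index
  tie_ann <- make_annotation("e1", "v", c(70, 150))
  tie <- match_expert_sequence(iv(100, 160), tie_ann)
  expect_equal(tie$intersection_s, 30)
  expect_equal(tie$expert_index, 1)

  expect_error(
    match_expert_sequence(x, expert_annotation("e", "v",
                                               data.frame(start_s = numeric(),
                                                          end_s = numeric()))),
    class = "gmaselect_validation_error"
  )
})

test_that("MDS is the best dice over raters and dominates subsets", {
  x <- iv(100, 160)
  experts <- list(
    make_annotation("a", "v", c(130)),        # dice 0.5
    make_annotation("b", "v", c(100)),        # dice 1
    make_annotation("c", "v", c(500))         # dice 0
  )
  expect_equal(max_dice_similarity(x, experts), 1)
  expect_equal(max_dice_similarity(x, experts[c(1, 3)]), 0.5)
  expect_equal(max_dice_similarity(x, experts[3]), 0)
  expect_error(max_dice_similarity(x, list()),
               class = "gmaselect_validation_error")

  # subset dominance on random panels
  for (seed in 1:10) {
    panel <- random_annotation_panel(1, 4, 5, seed = 40 + seed)
    set.seed(seed)
    s <- runif(1, 0, 540)
    x <- iv(s, s + 60)
    full <- max_dice_similarity(x, panel)
    for (drop in 1:4) {
      expect_gte(full, max_dice_similarity(x, panel[-drop]))
    }
    expect_equal(full, oracle_mds(x$start_s, x$end_s, panel))
  }
})

test_that("precision counts strict MDS exceedances over all selected sequences", {
  experts <- lapply(1:2, function(r) make_annotation(paste0("r", r), "v",
                                                     c(0, 100, 200)))
  perfect <- make_selection("v", c(0, 100, 200))
  expect_equal(precision(perfect, experts, 0.5), 1)
  expect_equal(precision(perfect, experts, 0.999), 1)
  expect_equal(precision(perfect, experts, 1), 0)      # strict inequality

  nowhere <- make_selection("v", c(400, 500))
  expect_equal(precision(nowhere, experts, 0), 0)      # MDS = 0 is not > 0

  # constructed fixture: 26 of 30 sequences exceed tau = 0.5
  sels <- lapply(1:6, function(v) {
    starts <- c(0, 100, 200, 300, 400)
    if (v <= 4) starts[1] <- 1000   # 4 sequences pushed out of agreement
    make_selection(paste0("v", v), starts, dur = 60)
  })
  anns <- unlist(lapply(1:6, function(v) {
    lapply(1:4, function(r) make_annotation(paste0("r", r), paste0("v", v),
                                            c(0, 100, 200, 300, 400) + 5))
  }), recursive = FALSE)
  expect_equal(precision(sels, anns, 0.5), 26 / 30)
  expect_equal(precision(sels, anns, 0.5), oracle_precision(sels, anns, 0.5))

  expect_error(precision(make_selection("ghost", 0), experts, 0.5),
               class = "gmaselect_validation_error")
})

test_that("precision curves are non-increasing step functions matching enumeration", {
  sels <- list(make_selection("v1", c(0, 100)), make_selection("v2", c(50)))
  anns <- unlist(lapply(c("v1", "v2"), function(v) {
    lapply(1:3, function(r) make_annotation(paste0("r", r), v,
                                            c(10, 95, 300)))
  }), recursive = FALSE)
  cv <- precision_curve(sels, anns)
  expect_s3_class(cv, "precision_curve")
  expect_equal(cv$n_sequences, 3)
  expect_true(all(diff(cv$precision) <= 0))
  for (t in c(0, 0.25, 0.5, 0.9)) {
    expect_equal(precision_at(cv, t), oracle_precision(sels, anns, t))
  }

  perfect <- precision_curve(make_selection("v1", c(10, 95)),
                             anns[1:3])
  expect_true(all(perfect$precision[perfect$tau < 1] == 1))
  expect_equal(perfect$precision[length(perfect$tau)], 0)

  flat0 <- precision_curve(make_selection("v1", 500), anns[1:3])
  expect_true(all(flat0$precision == 0))
})

test_that("leave-one-out drops exactly one rater at a time", {
  sels <- make_selection("v", c(0, 100, 200))
  same <- lapply(1:4, function(r) make_annotation(paste0("r", r), "v",
                                                  c(0, 100, 200)))
  loo <- leave_one_out_precision(sels, same)
  expect_named(loo, paste0("r", 1:4))
  full <- precision_curve(sels, same, warn_short = FALSE)
  for (cv in loo) expect_equal(cv$precision, full$precision)

  # an everywhere-disjoint rater changes nothing when excluded
  mixed <- c(same[1:3], list(make_annotation("r4", "v", c(400))))
  loo2 <- leave_one_out_precision(sels, mixed)
  expect_equal(loo2$r4$precision, precision_curve(sels, mixed[1:3],
                                                  warn_short = FALSE)$precision)

  expect_error(leave_one_out_precision(sels, same[1]),
               class = "gmaselect_validation_error")

  # brute-force recomputation per excluded rater on a random fixture
  panel <- random_annotation_panel(2, 4, 3, seed = 99)
  rsel <- list(make_selection("v1", c(30, 250)),
               make_selection("v2", c(10, 400)))
  loo3 <- leave_one_out_precision(rsel, panel, tau_grid = c(0.2, 0.5, 0.8))
  for (r in paste0("r", 1:4)) {
    rest <- Filter(function(a) a$rater_id != r, panel)
    for (i in 1:3) {
      expect_equal(loo3[[r]]$precision[i],
                   oracle_precision(rsel, rest, c(0.2, 0.5, 0.8)[i]))
    }
  }
})

test_that("inter-rater precision scores each rater against the rest", {
  twins <- lapply(1:2, function(r) make_annotation(paste0("r", r), "v",
                                                   c(0, 100)))
  ir <- inter_rater_precision(twins)
  for (cv in ir) {
    expect_true(all(cv$precision[cv$tau < 1] == 1))
    expect_equal(cv$n_sequences, 2)
  }

  apart <- list(make_annotation("r1", "v", c(0, 100)),
                make_annotation("r2", "v", c(300, 400)))
  for (cv in inter_rater_precision(apart)) {
    expect_true(all(cv$precision == 0))
  }

  # brute force on a jittered 4-rater panel
  panel <- random_annotation_panel(2, 4, 3, seed = 123)
  ir2 <- inter_rater_precision(panel, tau_grid = c(0.3, 0.6))
  for (r in paste0("r", 1:4)) {
    mine <- Filter(function(a) a$rater_id == r, panel)
    rest <- Filter(function(a) a$rater_id != r, panel)
    pseudo <- lapply(mine, function(a) {
      make_selection(a$video_id, a$intervals$start_s,
                     dur = a$intervals$end_s[1] - a$intervals$start_s[1])
    })
    expect_equal(ir2[[r]]$precision[1], oracle_precision(pseudo, rest, 0.3))
    expect_equal(ir2[[r]]$precision[2], oracle_precision(pseudo, rest, 0.6))
  }
})

test_that("curve averaging gives pointwise mean and population sd", {
  flat <- function(p) structure(
    list(tau = c(0, 0.5, 1), precision = rep(p, 3), n_sequences = 10L),
    class = "precision_curve"
  )
  avg <- average_curves(list(flat(1), flat(0)))
  expect_equal(avg$mean$precision, rep(0.5, 3))
  expect_equal(avg$sd$precision, rep(0.5, 3))

  same <- average_curves(list(flat(0.7), flat(0.7)))
  expect_equal(same$mean$precision, rep(0.7, 3))
  expect_equal(same$sd$precision, rep(0, 3))

  set.seed(4)
  curves <- lapply(1:5, function(i) structure(
    list(tau = seq(0, 1, 0.25), precision = runif(5), n_sequences = 1L),
    class = "precision_curve"
  ))
  avg2 <- average_curves(curves)
  m <- sapply(curves, `[[`, "precision")
  expect_equal(avg2$mean$precision, rowMeans(m))
  expect_equal(avg2$sd$precision,
               apply(m, 1, function(r) sqrt(mean((r - mean(r))^2))))

  bad <- structure(list(tau = c(0, 1), precision = c(1, 0),
                        n_sequences = 1L), class = "precision_curve")
  expect_error(average_curves(list(flat(1), bad)),
               class = "gmaselect_validation_error")
})

test_that("full evaluation report matches an exhaustive independent recomputation", {
  for (seed in c(7, 21)) {
    panel <- random_annotation_panel(3, 4, 4, seed = seed)
    set.seed(seed + 1)
    sels <- lapply(1:3, function(v) {
      make_selection(sprintf("v%d", v), runif(4, 0, 540))
    })
    report <- evaluate_selections(sels, panel, tau_grid = seq(0, 1, 0.1))
    expect_equal(nrow(report$per_sequence_mds), 12)
    for (i in seq_len(nrow(report$per_sequence_mds))) {
      row <- report$per_sequence_mds[i, ]
      sel <- sels[[match(row$video_id, sprintf("v%d", 1:3))]]
      mine <- Filter(function(a) a$video_id == row$video_id, panel)
      expect_equal(row$mds, oracle_mds(sel$intervals$start_s[row$rank],
                                       sel$intervals$end_s[row$rank], mine))
    }
    for (i in seq_along(report$meta$tau_grid)) {
      expect_equal(report$software_vs_experts$precision[i],
                   oracle_precision(sels, panel, report$meta$tau_grid[i]))
    }
    expect_equal(report$averages$software$mean$precision,
                 rowMeans(sapply(report$leave_one_out, `[[`, "precision")))
  }
})

test_that("report JSON and curve CSV exports are readable and faithful", {
  panel <- random_annotation_panel(2, 3, 3, seed = 5)
  sels <- list(make_selection("v1", c(10, 200)),
               make_selection("v2", c(100, 350)))
  report <- evaluate_selections(sels, panel, tau_grid = seq(0, 1, 0.05))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_report_json(report, jpath)
  back <- jsonlite::fromJSON(jpath)
  expect_equal(back$software_vs_experts$precision,
               report$software_vs_experts$precision)
  expect_equal(back$meta$n_experts, 3)
  expect_equal(nrow(back$per_sequence_mds), 4)

  cpath <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(report$software_vs_experts, cpath)
  df <- read.csv(cpath)
  expect_equal(df$precision, report$software_vs_experts$precision)
})
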