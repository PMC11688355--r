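# Synthetic pose-series generator: a static supine 17-keypoint template with
# Gaussian position jitter, planted high-motion bursts, and simulated expert
# raters who annotate the true bursts with jittered start times. Gives the
# selector and the evaluation stack an end-to-end testbed with known ground
# truth, which no clinical recording can provide.

#' Specify a planted motion burst
#'
#' @param start_s Burst onset, seconds from video start.
#' @param duration_s Burst duration, seconds, > 0.
#' @param amplitude_px Per-frame, per-keypoint displacement scale in pixels
#'   during the burst, > 0.
#' @return An object of class `burst_spec`.
#' @export
burst_spec <- function(start_s, duration_s, amplitude_px) {
  stopifnot(is_scalar_number(start_s), start_s >= 0,
            is_scalar_number(duration_s), duration_s > 0,
            is_scalar_number(amplitude_px), amplitude_px > 0)
  structure(list(start_s = start_s, duration_s = duration_s,
                 amplitude_px = amplitude_px),
            class = "burst_spec")
}

#' Configuration for the synthetic generator
#'
#' Bundles everything one simulated recording needs: its length and sampling
#' rate, the baseline per-keypoint Gaussian jitter representing pose-
#' estimator noise and minor infant motion, the planted bursts, the frame
#' geometry (default 1280 x 720), and the simulated rater panel (count,
#' start-time jitter, sequences per rater). A single seed fixes every random
#' draw, with per-expert sub-seeds so adding a rater never perturbs the
#' other streams.
#'
#' @param video_length_s Video length in whole seconds.
#' @param sample_rate_hz Pose sampling rate; default 1 Hz, the selector's
#'   native rate.
#' @param baseline_jitter_px Sd of per-keypoint Gaussian position noise,
#'   pixels, >= 0.
#' @param bursts List of [burst_spec()]; each must end by `video_length_s`.
#'   Overlapping bursts are permitted but flagged with a warning.
#' @param frame_width_px,frame_height_px Frame size in pixels.
#' @param n_experts Number of simulated raters.
#' @param expert_jitter_s Sd of Gaussian perturbation of each annotated
#'   start time, seconds, >= 0.
#' @param ns_per_expert Sequences each rater selects.
#' @param seed Integer root seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(video_length_s,
                              sample_rate_hz = 1,
                              baseline_jitter_px = 1,
                              bursts = list(),
                              frame_width_px = 1280,
                              frame_height_px = 720,
                              n_experts = 4,
                              expert_jitter_s = 5,
                              ns_per_expert = 5,
                              seed = 1) {
  stopifnot(is_scalar_number(video_length_s), video_length_s > 0,
            video_length_s == round(video_length_s),
            is_scalar_number(sample_rate_hz), sample_rate_hz > 0,
            is_scalar_number(baseline_jitter_px), baseline_jitter_px >= 0,
            is_scalar_number(expert_jitter_s), expert_jitter_s >= 0,
            is_scalar_number(n_experts), n_experts >= 0,
            is_scalar_number(ns_per_expert), ns_per_expert >= 1,
            is_scalar_number(seed))
  bursts <- lapply(bursts, function(b) {
    if (!inherits(b, "burst_spec")) b <- do.call(burst_spec, as.list(b))
    if (b$start_s + b$duration_s > video_length_s) {
      stop_gmaselect(
        sprintf("burst [%g, %g) extends past video end (%g s)",
                b$start_s, b$start_s + b$duration_s, video_length_s),
        "gmaselect_config_error"
      )
    }
    b
  })
  if (length(bursts) >= 2L) {
    ends <- vapply(bursts, function(b) b$start_s + b$duration_s, numeric(1))
    starts <- vapply(bursts, function(b) b$start_s, numeric(1))
    o <- order(starts)
    if (any(starts[o][-1] < ends[o][-length(o)])) {
      warning("overlapping bursts in simulation config", call. = FALSE)
    }
  }
  structure(
    list(video_length_s = as.integer(video_length_s),
         sample_rate_hz = sample_rate_hz,
         baseline_jitter_px = baseline_jitter_px,
         bursts = bursts,
         frame_width_px = as.integer(frame_width_px),
         frame_height_px = as.integer(frame_height_px),
         n_experts = as.integer(n_experts),
         expert_jitter_s = expert_jitter_s,
         ns_per_expert = as.integer(ns_per_expert),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Supine infant template, 17 COCO keypoints, centred for a 1280 x 720 frame;
# rescaled to other frame sizes. Anatomical realism is irrelevant to the
# displacement sum, so the template is static apart from noise.
supine_template <- function(width, height) {
  base <- matrix(c(
    640, 250,   # nose
    625, 240, 655, 240,   # eyes
    608, 248, 672, 248,   # ears
    590, 300, 690, 300,   # shoulders
    560, 360, 720, 360,   # elbows
    545, 420, 735, 420,   # wrists
    612, 430, 668, 430,   # hips
    595, 505, 685, 505,   # knees
    585, 575, 695, 575    # ankles
  ), ncol = 2, byrow = TRUE)
  cbind(base[, 1] * width / 1280, base[, 2] * height / 720)
}

#' Generate a synthetic pose series with planted bursts
#'
#' Keypoints sit on a fixed supine template plus per-frame Gaussian jitter
#' (sd `baseline_jitter_px`). During a burst every keypoint additionally
#' moves by a random-direction displacement whose magnitude is drawn from
#' |Normal(amplitude, amplitude/4)|, frame by frame, so consecutive burst
#' frames differ by roughly the amplitude per keypoint. Coordinates are
#' clamped to the frame. Fully deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @param video_id Identifier for the generated series.
#' @return List with `series` (a `pose_series`) and `truth` (data frame of
#'   the planted burst intervals: `start_s`, `end_s`, `amplitude_px`).
#' @export
generate_pose_series <- function(config, video_id = "sim_video") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  rate <- config$sample_rate_hz
  time_s <- seq(0, config$video_length_s, by = 1 / rate)
  nf <- length(time_s)
  tmpl <- supine_template(config$frame_width_px, config$frame_height_px)

  x <- matrix(rep(tmpl[, 1], each = nf), nf, N_KEYPOINTS) +
    matrix(rnorm(nf * N_KEYPOINTS, 0, config$baseline_jitter_px),
           nf, N_KEYPOINTS)
  y <- matrix(rep(tmpl[, 2], each = nf), nf, N_KEYPOINTS) +
    matrix(rnorm(nf * N_KEYPOINTS, 0, config$baseline_jitter_px),
           nf, N_KEYPOINTS)

  for (b in config$bursts) {
    inside <- which(time_s >= b$start_s & time_s < b$start_s + b$duration_s)
    if (!length(inside)) next
    n <- length(inside) * N_KEYPOINTS
    mag <- abs(rnorm(n, b$amplitude_px, b$amplitude_px / 4))
    ang <- runif(n, 0, 2 * pi)
    x[inside, ] <- x[inside, ] + matrix(mag * cos(ang), length(inside))
    y[inside, ] <- y[inside, ] + matrix(mag * sin(ang), length(inside))
  }
  x <- pmin(pmax(x, 0), config$frame_width_px)
  y <- pmin(pmax(y, 0), config$frame_height_px)
  conf <- matrix(runif(nf * N_KEYPOINTS, 0.7, 1), nf, N_KEYPOINTS)

  truth <- if (length(config$bursts)) {
    data.frame(
      start_s = vapply(config$bursts, `[[`, numeric(1), "start_s"),
      end_s = vapply(config$bursts, function(b) b$start_s + b$duration_s,
                     numeric(1)),
      amplitude_px = vapply(config$bursts, `[[`, numeric(1), "amplitude_px")
    )
  } else {
    data.frame(start_s = numeric(), end_s = numeric(),
               amplitude_px = numeric())
  }
  list(
    series = pose_series(video_id, time_s, x, y, conf,
                         sample_rate_hz = rate,
                         frame_width_px = config$frame_width_px,
                         frame_height_px = config$frame_height_px),
    truth = truth
  )
}

expert_subseed <- function(seed, e) {
  as.integer((as.numeric(seed) * 1000 + 7919 * e) %% 2147483647)
}

#' Simulate expert annotations of the planted bursts
#'
#' Raters are modelled as jittered oracles: each selects the
#' `ns_per_expert` largest-amplitude true bursts and perturbs every start
#' time by Normal(0, `expert_jitter_s`), clamped so the interval stays
#' inside the video. If more sequences are requested than bursts exist, the
#' rater pads with uniformly placed random intervals and the result carries
#' a `padded` attribute (and a warning). Each rater draws from its own
#' sub-seed, so annotations are reproducible and rater streams independent.
#'
#' @param truth Data frame of true bursts as returned by
#'   [generate_pose_series()] (`start_s`, `end_s`, `amplitude_px`).
#' @param config The same [simulation_config()].
#' @param video_id Video the annotations refer to.
#' @return List of [expert_annotation()], raters named `expert_1`, ...
#' @export
generate_expert_annotations <- function(truth, config,
                                        video_id = "sim_video") {
  stopifnot(inherits(config, "simulation_config"))
  dur_total <- config$video_length_s
  ord <- order(-truth$amplitude_px, truth$start_s)
  ranked <- truth[ord, , drop = FALSE]
  n_real <- min(config$ns_per_expert, nrow(ranked))
  n_pad <- config$ns_per_expert - n_real
  if (n_pad > 0) {
    warning(sprintf(
      "%d sequence(s) per expert requested but only %d burst(s) planted; padding with random intervals",
      config$ns_per_expert, nrow(ranked)
    ), call. = FALSE)
  }
  lapply(seq_len(config$n_experts), function(e) {
    set.seed(expert_subseed(config$seed, e))
    starts <- ranked$start_s[seq_len(n_real)]
    durs <- (ranked$end_s - ranked$start_s)[seq_len(n_real)]
    jit <- rnorm(n_real, 0, config$expert_jitter_s)
    starts <- pmin(pmax(starts + jit, 0), dur_total - durs)
    iv <- data.frame(start_s = starts, end_s = starts + durs)
    if (n_pad > 0) {
      pad_dur <- if (n_real > 0) durs[1] else min(60, dur_total)
      ps <- runif(n_pad, 0, dur_total - pad_dur)
      iv <- rbind(iv, data.frame(start_s = ps, end_s = ps + pad_dur))
    }
    ann <- expert_annotation(sprintf("expert_%d", e), video_id, iv)
    attr(ann, "padded") <- n_pad
    ann
  })
}

#' Configurations for the standard validation study
#'
#' The package's reference end-to-end scenario: `n_videos` ten-minute
#' recordings at 1 Hz, each with five well-separated 60 s bursts of distinct
#' amplitudes (15-25 px per frame per keypoint) over 1 px baseline jitter,
#' annotated by four simulated raters with 5 s start-time jitter selecting
#' five sequences each — mirroring the operating point at which automatic
#' and expert selections are compared (5 one-minute sequences per video, 6
#' videos, 4 raters). See the methods vignette for the rationale behind
#' each value.
#'
#' @param seed Root seed; video v uses `seed + v`.
#' @param n_videos Number of simulated recordings.
#' @return Named list of [simulation_config()], one per video.
#' @export
validation_study_configs <- function(seed = 1, n_videos = 6) {
  starts <- c(30, 150, 270, 390, 510)
  amps <- c(25, 22, 19, 17, 15)
  cfgs <- lapply(seq_len(n_videos), function(v) {
    simulation_config(
      video_length_s = 600,
      sample_rate_hz = 1,
      baseline_jitter_px = 1,
      bursts = Map(function(s, a) burst_spec(s, 60, a), starts, amps),
      n_experts = 4,
      expert_jitter_s = 5,
      ns_per_expert = 5,
      seed = seed + v
    )
  })
  setNames(cfgs, sprintf("video_%d", seq_len(n_videos)))
}

#' Read a simulation config from a YAML file
#'
#' Schema: top-level keys are the arguments of [simulation_config()];
#' `bursts` is a list of mappings with `start_s`, `duration_s`,
#' `amplitude_px`.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) {
    stop_gmaselect(sprintf("file not found: %s", path), "gmaselect_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$bursts)) {
    raw$bursts <- lapply(raw$bursts, function(b) do.call(burst_spec, b))
  }
  do.call(simulation_config, raw)
}

#' Write a simulated dataset to disk
#'
#' Generates one recording and its simulated annotations and writes
#' `pose.csv` (keypoint table), `truth.csv` (planted bursts),
#' `annotations.csv` (rater intervals) and `manifest.json` (seed and full
#' config) into `out_dir`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory; must be empty or absent unless
#'   `force = TRUE`.
#' @param video_id Identifier for the simulated video.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_dataset <- function(config, out_dir, video_id = "sim_video",
                             force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop_gmaselect(
      sprintf("output directory %s is not empty (use force = TRUE)", out_dir),
      "gmaselect_io_error"
    )
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_pose_series(config, video_id)
  anns <- generate_expert_annotations(sim$truth, config, video_id)
  paths <- list(
    pose = file.path(out_dir, "pose.csv"),
    truth = file.path(out_dir, "truth.csv"),
    annotations = file.path(out_dir, "annotations.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_pose_table(sim$series, paths$pose, "csv")
  utils::write.csv(cbind(video_id = video_id, sim$truth), paths$truth,
                   row.names = FALSE, quote = FALSE)
  write_annotations(anns, paths$annotations)
  manifest <- list(seed = config$seed, video_id = video_id,
                   config = unclass(config))
  manifest$config$bursts <- lapply(config$bursts, unclass)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
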