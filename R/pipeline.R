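## Orchestration: route each subject through the appropriate smart-annotation
## method and run the iterative batch study on synthetic data.

#' Annotate one subject bundle
#'
#' Routes tasks to the chosen smart-annotation method: `"edge"` (pressure
#' edge detection; needs insole data), `"hhmm"` (needs a trained model),
#' `"pd"` or `"lce"` (unsupervised cycle detectors, used for phase-less
#' cycling tasks; cycling tasks are always routed to a cycle detector, even
#' under the other methods). Returns post-processed per-foot tracks with a
#' per-segment `method` provenance column, plus evaluation reports when the
#' bundle carries ground truth.
#'
#' @param subject Subject bundle as from [generate_subject()]: `imu_left`,
#'   `imu_right`, `insole_left`, `insole_right`, `tasks`, optional `truth`.
#' @param method One of `"edge"`, `"hhmm"`, `"pd"`, `"lce"`.
#' @param model Trained `HhmmModel` (required for `method = "hhmm"`).
#' @param config Configuration list.
#' @return List with `tracks` (per foot) and, if truth is present, `reports`.
#' @export
run_annotation <- function(subject, method = c("edge", "hhmm", "pd", "lce"),
                           model = NULL, config = default_config()) {
  method <- match.arg(method)
  if (method == "hhmm" && is.null(model)) {
    stop("method 'hhmm' requires a trained model")
  }
  if (method == "edge" && is.null(subject$insole_left)) {
    stop("method 'edge' requires pressure insole data")
  }
  tasks <- subject$tasks
  is_cycle_task <- vapply(tasks$allowed_activities,
                          function(a) "cycle" %in% a, logical(1))
  tracks <- list()
  for (foot in c("left", "right")) {
    imu <- subject[[paste0("imu_", foot)]]
    segs <- NULL
    prov <- character(0)
    # cyclic-phase tasks
    if (any(!is_cycle_task)) {
      main <- if (method %in% c("pd", "lce")) "hhmm_missing" else method
      tr <- switch(
        method,
        edge = edge_detect_track(subject[[paste0("insole_", foot)]], imu,
                                 tasks[!is_cycle_task, , drop = FALSE],
                                 foot = foot, config = config),
        hhmm = {
          fm <- extract_features(imu, config$features$window_s,
                                 config$features$step_s)
          fm$frames <- normalize_per_person(fm$frames)
          hhmm_predict(model, fm, tasks[!is_cycle_task, , drop = FALSE],
                       foot = foot)
        },
        stop("phase-labeled tasks require method 'edge' or 'hhmm'")
      )
      segs <- rbind(segs, tr$segments)
      prov <- c(prov, rep(method, nrow(tr$segments)))
    }
    # phase-less cycling tasks -> cycle detector
    if (any(is_cycle_task)) {
      det <- if (method == "lce") "lce" else "pd"
      # light smoothing before peak picking so anchors sit on the motion
      # peak rather than a noise spike; then max-abs normalize
      gz <- normalize_maxabs(lowpass(imu, config$pd$smooth_cutoff_hz), "GZ")
      rm_mask <- rest_mask(imu, config$rest$window_s, config$rest$threshold)
      for (i in which(is_cycle_task)) {
        gzv <- ts_channel(gz, "GZ")
        marks <- if (det == "pd") {
          detect_pd(gzv, imu$rate_hz, config$pd$min_distance_s,
                    config$pd$min_height)
        } else {
          detect_lce(gzv, imu$rate_hz, config$lce$noise_threshold,
                     config$lce$f_min, config$lce$f_max)
        }
        tr <- marks_to_track(marks, rm_mask, imu$rate_hz,
                             tasks[i, , drop = FALSE], foot = foot)
        segs <- rbind(segs, tr$segments)
        prov <- c(prov, rep(det, nrow(tr$segments)))
      }
    }
    if (is.null(segs)) {
      tracks[[foot]] <- label_track(NULL, foot = foot)
    } else {
      ord <- order(segs$start_s)
      segs <- segs[ord, , drop = FALSE]
      tr <- label_track(segs, foot = foot)
      tr$segments$method <- prov[ord]
      tracks[[foot]] <- tr
    }
  }
  out <- list(tracks = tracks)
  if (!is.null(subject$truth)) {
    out$reports <- lapply(c(left = "left", right = "right"), function(f) {
      evaluate_tracks(tracks[[f]], subject$truth[[f]])
    })
  }
  out
}

subject_to_corpus_items <- function(subject, config) {
  lapply(c("left", "right"), function(foot) {
    imu <- subject[[paste0("imu_", foot)]]
    fm <- extract_features(imu, config$features$window_s,
                           config$features$step_s)
    fm$frames <- normalize_per_person(fm$frames)
    list(features = fm, track = subject$truth[[foot]], tasks = subject$tasks)
  })
}

#' Run the iterative smart-annotation study on synthetic data
#'
#' Emulates the dataset-labeling workflow: batch 1 is annotated by pressure
#' edge detection and scored against ground truth; its (corrected = true)
#' labels train an hHMM that predicts batch 2; each later batch is predicted
#' with the previous model, scored, and added to the training set. Every
#' intermediate model also predicts the final batch's subjects (the fixed
#' holdout), giving the per-model learning curve.
#'
#' @param n_batches Number of batches (default 7).
#' @param batch_size Subjects per batch (default 3).
#' @param seed Master seed; all randomness derives from it.
#' @param scenario Base `SubjectScenario` for all subjects.
#' @param n_iterations hHMM training iterations per stage.
#' @param config Configuration list.
#' @return List of class `IterativeStudy`: `edge_reports` (batch 1, per
#'   subject-foot), `batch_reports` (batches 2..n), `holdout_reports` (per
#'   model), `summary` (data.frame of mean effort/F1 per stage), `models`.
#' @export
run_iterative_study <- function(n_batches = 7, batch_size = 3, seed = 1,
                                scenario = subject_scenario(),
                                n_iterations = 100,
                                config = default_config()) {
  set.seed(seed)
  batch_seeds <- sample.int(2^31 - 2, n_batches)
  subjects <- lapply(seq_len(n_batches), function(k) {
    generate_batch(batch_size, batch_seeds[k], scenario = scenario)
  })
  # batch 1: edge detection
  edge_reports <- unlist(lapply(subjects[[1]], function(sub) {
    run_annotation(sub, "edge", config = config)$reports
  }), recursive = FALSE)
  # corpora for the hHMM stages
  corpora <- lapply(subjects, function(batch) {
    do.call(c, lapply(batch, subject_to_corpus_items, config = config))
  })
  proto <- iterative_protocol(corpora, n_iterations = n_iterations,
                              holdout = corpora[[n_batches]],
                              variance_floor = config$hhmm$variance_floor)
  stage_summary <- function(reports) {
    agg <- aggregate_reports(reports)
    c(effort = agg$mean[agg$metric == "effort"],
      f1 = agg$mean[agg$metric == "f1"])
  }
  summ <- rbind(
    data.frame(stage = "batch1_edge", t(stage_summary(edge_reports))),
    do.call(rbind, lapply(2:n_batches, function(k) {
      data.frame(stage = sprintf("batch%d_hhmm", k),
                 t(stage_summary(proto$batch_reports[[k]])))
    })),
    do.call(rbind, lapply(seq_along(proto$models), function(k) {
      data.frame(stage = sprintf("holdout_model%d", k),
                 t(stage_summary(proto$holdout_reports[[k]])))
    }))
  )
  structure(list(edge_reports = edge_reports,
                 batch_reports = proto$batch_reports,
                 holdout_reports = proto$holdout_reports,
                 summary = summ, models = proto$models),
            class = "IterativeStudy")
}

#' @export
print.IterativeStudy <- function(x, ...) {
  cat("<IterativeStudy>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
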