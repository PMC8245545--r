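# End-to-end orchestration: simulate -> crop -> detect -> extract ROIs ->
# code features -> select -> LOEO classification -> cooperative decisions.

#' Pipeline configuration
#'
#' Bundles every stage's parameters plus the single global seed all
#' randomness flows from. A persisted config re-runs to identical outputs.
#'
#' @param counts named per-condition video counts for the simulated cohort.
#' @param video list of overrides for [synthetic_config()] (e.g.
#'   `n_frames`, `frame_size`, `n_cells`).
#' @param abnormal_fraction optional per-condition abnormal-fraction
#'   override passed to [generate_cohort()].
#' @param half_width crop half-width around the barrier, px.
#' @param roi_size ROI side, px.
#' @param sensitivity Hough accumulator threshold.
#' @param min_score detection-quality floor applied when keeping
#'   post-barrier ROIs (weak accumulator responses are mostly spurious).
#' @param backend feature backend name or [feature_backend()].
#' @param selection `list(mode =, value =)` for the per-fold low-variance
#'   filter, or `NULL` to disable. With the compact handcrafted descriptor
#'   set the default drops only (near-)constant columns; the factor-50
#'   target is meant for wide CNN codings.
#' @param problem `"two_class"` or `"four_class"`.
#' @param rules list of decision rules to evaluate, each
#'   `list(rule =, limit =)`.
#' @param cost SVM regularisation constant.
#' @param seed global integer seed.
#' @param out_dir optional directory for report and CSV artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = c(healthy = 6, SCD = 2, THAL = 2, HS = 2),
                            video = list(),
                            abnormal_fraction = NULL,
                            half_width = 72L,
                            roi_size = 32L,
                            sensitivity = 0.3,
                            min_score = 0.5,
                            backend = "handcrafted",
                            selection = list(mode = "threshold", value = 1e-8),
                            problem = c("two_class", "four_class"),
                            rules = list(list(rule = "majority"),
                                         list(rule = "percentage_limit", limit = 0.30),
                                         list(rule = "percentage_limit", limit = 0.40),
                                         list(rule = "max_trustiness")),
                            cost = 1,
                            seed = 1L,
                            out_dir = NULL) {
  problem <- match.arg(problem)
  structure(list(counts = counts, video = video,
                 abnormal_fraction = abnormal_fraction,
                 half_width = half_width,
                 roi_size = roi_size, sensitivity = sensitivity,
                 min_score = min_score,
                 backend = backend, selection = selection, problem = problem,
                 rules = rules, cost = cost, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full video-classification pipeline
#'
#' Simulates (or accepts) a cohort, crops every video to the barrier region,
#' detects cells with the circular Hough transform, extracts post-barrier
#' ROIs, codes them with the configured backend, scores them under LOEO
#' cross-validation, and aggregates per-video decisions under every
#' configured rule. Videos yielding no post-barrier ROI are flagged
#' undecidable, excluded from the confusion matrices, and counted in the
#' report.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built cohort (list of `list(video, truth)` as
#'   from [generate_cohort()]); when `NULL` one is simulated from
#'   `config$counts` and `config$seed`.
#' @return A run report (list) with the confusion matrix, efficiency and
#'   decisions per rule, the fold manifest, per-ROI accuracy, the
#'   ROI-count table, detection quality against ground truth, and the
#'   feature reduction factor. When `config$out_dir` is set the report and
#'   CSV intermediates are written there.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    base <- do.call(synthetic_config, config$video)
    cohort <- generate_cohort(config$counts, base, seed = config$seed,
                              abnormal_fraction = config$abnormal_fraction)
  }
  if (length(cohort) < 2L) {
    abort("pipeline needs at least 2 videos", "slitflow_config_error")
  }
  conditions <- vapply(cohort, function(x) x$truth$condition, character(1))
  names(conditions) <- vapply(cohort, function(x) x$video$video_id, character(1))

  radius_mean <- if (!is.null(config$video$cell_radius_px))
    unname(config$video$cell_radius_px["mean"]) else 8
  rr <- hough_radii(radius_mean)

  roi_sets <- list()
  undecided <- character(0)
  det_eligible <- 0L; det_matched <- 0L; det_err_sum <- 0
  for (nm in names(cohort)) {
    item <- cohort[[nm]]
    vc <- crop_to_barrier_region(item$video, config$half_width)
    tshift <- shift_truth(item$truth, vc$col_offset)
    det <- detect_video(vc, rr[1], rr[2], sensitivity = config$sensitivity)
    q <- evaluate_detection(det, tshift, dim(vc$frames[[1]]))
    if (q$n_eligible > 0L) {
      det_eligible <- det_eligible + q$n_eligible
      det_matched <- det_matched + q$n_matched
      if (q$n_matched > 0L) {
        det_err_sum <- det_err_sum + q$mean_center_error * q$n_matched
      }
    }
    rois <- extract_rois(vc, det, config$roi_size, vc$barrier_x)
    after <- filter_rois(rois, "after", min_score = config$min_score %||% 0)
    if (nrow(after$info) == 0L) {
      undecided <- c(undecided, item$video$video_id)
    } else {
      roi_sets[[nm]] <- after
    }
  }
  if (length(roi_sets) < 2L) {
    abort("fewer than 2 videos produced post-barrier ROIs", "slitflow_fold_error")
  }
  all_rois <- bind_rois(roi_sets)
  features <- extract_features(all_rois, config$backend)

  video_labels <- condition_to_label(conditions, config$problem)
  names(video_labels) <- names(conditions)

  rules <- config$rules
  if (config$problem == "four_class") {
    drop <- vapply(rules, function(r) r$rule == "percentage_limit", logical(1))
    if (any(drop)) {
      warning("percentage_limit applies to the two-class problem only; rule dropped")
      rules <- rules[!drop]
    }
  }

  loeo <- run_loeo(features, features$roi_index$video_id, video_labels,
                   problem = config$problem, selection = config$selection,
                   cost = config$cost)
  preds <- loeo$predictions
  per_roi_acc <- mean(preds$label == video_labels[preds$video_id])

  classes <- problem_classes(config$problem)
  decided_videos <- unique(preds$video_id)
  rule_reports <- lapply(rules, function(r) {
    dec <- decide_videos(preds, r$rule, limit = r$limit %||% 0.30)
    cm <- build_confusion(dec, video_labels[decided_videos], classes)
    list(rule = r$rule, parameter = r$limit %||% NA_real_,
         decisions = dec, confusion = cm, efficiency = efficiency(cm))
  })
  names(rule_reports) <- vapply(rules, function(r)
    if (r$rule == "percentage_limit")
      sprintf("percentage_limit_%02d", round(100 * (r$limit %||% 0.30)))
    else r$rule, character(1))

  tbl <- roi_count_table(conditions, features$roi_index$video_id)
  validate_roi_table(tbl)
  retained <- loeo$folds$n_features_retained
  reduction_factor <- ncol(features$matrix) /
    mean(retained[!is.na(retained)])

  report <- list(
    config = config,
    n_videos = length(cohort),
    undecided = undecided,
    roi_table = tbl,
    folds = loeo$folds,
    skipped_folds = loeo$skipped,
    per_roi_accuracy = per_roi_acc,
    detection = list(
      recall = if (det_eligible > 0) det_matched / det_eligible else NA_real_,
      mean_center_error = if (det_matched > 0) det_err_sum / det_matched
                          else NA_real_,
      n_eligible = det_eligible),
    reduction_factor = reduction_factor,
    rules = rule_reports,
    video_labels = video_labels,
    conditions = conditions,
    features = features,
    predictions = preds)

  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roi_table, file.path(out_dir, "roi_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$folds, file.path(out_dir, "fold_manifest.csv"),
                   row.names = FALSE)
  dec <- do.call(rbind, lapply(report$rules, function(r) r$decisions))
  utils::write.csv(dec, file.path(out_dir, "decisions.csv"), row.names = FALSE)
  summary <- list(
    n_videos = report$n_videos,
    undecided = report$undecided,
    per_roi_accuracy = report$per_roi_accuracy,
    detection = report$detection,
    reduction_factor = report$reduction_factor,
    efficiencies = lapply(report$rules, function(r) r$efficiency),
    confusions = lapply(report$rules, function(r) unclass(r$confusion)),
    seed = report$config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
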