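# Leave-one-experiment-out (LOEO) cross-validation: all ROIs of one video
# are held out per fold, the rest train the model.

#' Fold bookkeeping for a leave-one-video-out split
#'
#' One fold per video: the fold's test rows are the video's ROIs, its
#' training rows are every other ROI.
#'
#' @param video_ids character vector mapping each ROI to its video.
#' @return Data frame with `video_id`, `n_test`, `n_train` per fold, in
#'   order of first appearance.
#' @export
fold_manifest <- function(video_ids) {
  ids <- unique(video_ids)
  n_test <- vapply(ids, function(v) sum(video_ids == v), integer(1))
  data.frame(video_id = ids, n_test = n_test,
             n_train = length(video_ids) - n_test,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Leave-one-experiment-out cross-validated scoring
#'
#' Repeats exhaustively over all videos: per fold, the held-out video's ROIs
#' are scored by a pipeline fitted on the remaining ROIs only — the
#' low-variance selection mask, the feature standardisation and the linear
#' SVM are all estimated on training rows, so nothing leaks from the
#' held-out video. Folds whose training partition collapses to a single
#' class are skipped with a warning and reported.
#'
#' @param features a `feature_table` covering every ROI.
#' @param video_ids character vector aligned with feature rows.
#' @param video_labels named integer vector (or named map) of per-video
#'   class labels.
#' @param problem `"two_class"` or `"four_class"`.
#' @param selection `NULL` to skip feature selection, or
#'   `list(mode =, value =)` passed to [fit_low_variance_mask()] per fold.
#' @param cost SVM regularisation constant.
#' @param class_weights passed to [train_classifier()].
#' @return A list: `predictions` (`scored_predictions` for every scored ROI,
#'   in the original row order), `folds` (manifest with per-fold training
#'   row counts and retained feature counts), `skipped` (video ids of
#'   skipped folds), `masks` (per-fold selection masks, named by video).
#' @export
run_loeo <- function(features, video_ids, video_labels,
                     problem = c("two_class", "four_class"),
                     selection = list(mode = "target_factor", value = 50),
                     cost = 1, class_weights = NULL) {
  problem <- match.arg(problem)
  stopifnot(inherits(features, "feature_table"))
  n <- nrow(features$matrix)
  if (length(video_ids) != n) {
    abort("video_ids must align with feature rows", "slitflow_shape_error")
  }
  video_labels <- unlist(video_labels)
  unmapped <- setdiff(unique(video_ids), names(video_labels))
  if (length(unmapped)) {
    abort(sprintf("no label for video(s): %s", paste(unmapped, collapse = ", ")),
          "slitflow_fold_error")
  }
  ids <- unique(video_ids)
  if (length(ids) < 2L) {
    abort("LOEO needs at least 2 videos", "slitflow_fold_error")
  }

  preds <- vector("list", length(ids))
  masks <- vector("list", length(ids))
  skipped <- character(0)
  manifest <- fold_manifest(video_ids)
  manifest$n_features_retained <- NA_integer_
  manifest$n_train_classes <- NA_integer_

  for (i in seq_along(ids)) {
    v <- ids[i]
    tr <- video_ids != v
    te <- !tr
    lab_tr <- unname(video_labels[video_ids[tr]])
    manifest$n_train_classes[i] <- length(unique(lab_tr))
    if (length(unique(lab_tr)) < 2L) {
      warning(sprintf("fold '%s' skipped: single-class training partition", v))
      skipped <- c(skipped, v)
      next
    }
    f_tr <- subset_feature_rows(features, tr)
    f_te <- subset_feature_rows(features, te)
    if (!is.null(selection)) {
      mask <- fit_low_variance_mask(f_tr, mode = selection$mode,
                                    value = selection$value)
      masks[[i]] <- mask
      f_tr <- apply_mask(f_tr, mask)
      f_te <- apply_mask(f_te, mask)
      manifest$n_features_retained[i] <- sum(mask$retained)
    } else {
      manifest$n_features_retained[i] <- ncol(features$matrix)
    }
    model <- train_classifier(f_tr, lab_tr, problem, cost = cost,
                              class_weights = class_weights)
    preds[[i]] <- predict(model, f_te)
  }
  names(masks) <- ids

  scored <- preds[!vapply(preds, is.null, logical(1))]
  predictions <- if (length(scored)) do.call(rbind, scored) else NULL
  if (!is.null(predictions)) {
    # restore the original ROI order
    predictions <- predictions[order(match(predictions$roi_id,
                                           features$roi_index$roi_id)), ]
    rownames(predictions) <- NULL
    attr(predictions, "class_labels") <- problem_classes(problem)
    class(predictions) <- c("scored_predictions", "data.frame")
  }
  list(predictions = predictions, folds = manifest, skipped = skipped,
       masks = masks)
}
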