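# Cooperative video-level decision rules: majority voting,
# unhealthy-percentage limit, maximum trustiness; plus confusion-matrix and
# efficiency reporting.

one_video <- function(predictions) {
  v <- unique(predictions$video_id)
  if (length(v) > 1L) {
    abort("predictions span several videos; split by video first",
          "slitflow_usage_error")
  }
  if (nrow(predictions) == 0L) {
    abort("no predictions for this video: undecidable",
          "slitflow_decision_error")
  }
  v
}

video_decision <- function(video_id, rule, decided, evidence,
                           parameter = NA_real_, n_rois = NA_integer_,
                           normalized_score = NA_real_) {
  structure(list(video_id = video_id, rule = rule,
                 decided_class = decided, evidence = evidence,
                 parameter = parameter, n_rois = n_rois,
                 normalized_score = normalized_score),
            class = "video_decision")
}

#' @export
print.video_decision <- function(x, ...) {
  cat(sprintf("video '%s' -> class %s by %s%s\n", x$video_id,
              x$decided_class, x$rule,
              if (!is.na(x$parameter)) sprintf(" (limit %.2f)", x$parameter) else ""))
  invisible(x)
}

#' Majority vote over a video's per-ROI labels
#'
#' Assigns the modal per-ROI label to the video. Ties are broken first by
#' the larger per-class score total over the video's ROIs, then by the lower
#' class index; the full vote counts are kept as evidence.
#'
#' @param predictions `scored_predictions` rows of one video.
#' @return A `video_decision`.
#' @export
majority_vote <- function(predictions) {
  v <- one_video(predictions)
  classes <- prediction_classes(predictions)
  votes <- vapply(classes, function(cl) sum(predictions$label == cl), integer(1))
  names(votes) <- classes
  top <- which(votes == max(votes))
  if (length(top) > 1L) {
    totals <- vapply(classes[top], function(cl)
      sum(predictions[[paste0("score_", cl)]]), numeric(1))
    top <- top[totals == max(totals)]
  }
  video_decision(v, "majority", classes[top[1L]], votes,
                 n_rois = nrow(predictions))
}

#' Unhealthy-percentage-limit rule (two-class)
#'
#' The video is labelled unhealthy (class 1) iff the fraction of its ROIs
#' assigned to class 1 *strictly* exceeds `limit` (e.g. 0.30, 0.40), else
#' healthy. A high-sensitivity screening rule: at the 30% limit the platform
#' is tuned never to miss a disease video.
#'
#' @param predictions two-class `scored_predictions` rows of one video.
#' @param limit fraction in (0, 1).
#' @return A `video_decision`.
#' @export
percentage_limit <- function(predictions, limit = 0.30) {
  v <- one_video(predictions)
  classes <- prediction_classes(predictions)
  if (length(classes) != 2L || !all(classes == 0:1)) {
    abort("percentage_limit applies to two-class predictions only",
          "slitflow_usage_error")
  }
  if (!is.numeric(limit) || length(limit) != 1L || limit <= 0 || limit >= 1) {
    abort("limit must lie strictly between 0 and 1", "slitflow_usage_error")
  }
  votes <- c(`0` = sum(predictions$label == 0L),
             `1` = sum(predictions$label == 1L))
  frac <- votes[["1"]] / nrow(predictions)
  video_decision(v, "percentage_limit", as.integer(frac > limit), votes,
                 parameter = limit, n_rois = nrow(predictions))
}

#' Maximum-trustiness rule
#'
#' Sums each class's normalised scores over all the video's ROIs and assigns
#' the class with the highest sum (ties to the lower class index). Because
#' per-ROI scores sum to one, the per-class sums total the ROI count; the
#' reported normalised score of the decision is the winning sum divided by
#' the ROI count.
#'
#' @param predictions `scored_predictions` rows of one video.
#' @return A `video_decision` (with `normalized_score`).
#' @export
max_trustiness <- function(predictions) {
  v <- one_video(predictions)
  classes <- prediction_classes(predictions)
  sums <- vapply(classes, function(cl)
    sum(predictions[[paste0("score_", cl)]]), numeric(1))
  names(sums) <- classes
  k <- which.max(sums)            # which.max takes the first (lowest index)
  video_decision(v, "max_trustiness", classes[k], sums,
                 n_rois = nrow(predictions),
                 normalized_score = sums[[k]] / nrow(predictions))
}

#' Apply a decision rule to every video of a prediction set
#'
#' @param predictions `scored_predictions` for a cohort.
#' @param rule `"majority"`, `"percentage_limit"` or `"max_trustiness"`.
#' @param limit percentage limit for `"percentage_limit"`.
#' @return Data frame with one row per video (`video_id`, `rule`,
#'   `parameter`, `decided`, `n_rois`, `normalized_score`); per-video
#'   evidence vectors are kept in the `"evidence"` attribute.
#' @export
decide_videos <- function(predictions,
                          rule = c("majority", "percentage_limit",
                                   "max_trustiness"),
                          limit = 0.30) {
  rule <- match.arg(rule)
  classes <- prediction_classes(predictions)
  split_idx <- split(seq_len(nrow(predictions)), predictions$video_id)
  split_idx <- split_idx[unique(predictions$video_id)]   # keep cohort order
  decisions <- lapply(split_idx, function(idx) {
    p <- predictions[idx, , drop = FALSE]
    attr(p, "class_labels") <- classes
    switch(rule,
           majority = majority_vote(p),
           percentage_limit = percentage_limit(p, limit),
           max_trustiness = max_trustiness(p))
  })
  out <- data.frame(
    video_id = vapply(decisions, `[[`, character(1), "video_id"),
    rule = rule,
    parameter = if (rule == "percentage_limit") limit else NA_real_,
    decided = vapply(decisions, function(d) as.integer(d$decided_class),
                     integer(1)),
    n_rois = vapply(decisions, `[[`, integer(1), "n_rois"),
    normalized_score = vapply(decisions, `[[`, numeric(1), "normalized_score"),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "evidence") <- lapply(decisions, `[[`, "evidence")
  attr(out, "class_labels") <- classes
  out
}

#' Build a video-level confusion matrix
#'
#' Rows are true classes, columns decided classes; entries sum to the number
#' of decided videos.
#'
#' @param decisions data frame from [decide_videos()] (needs `video_id`,
#'   `decided`).
#' @param truth named vector mapping video ids to true class labels.
#' @param classes ordered class labels.
#' @return Integer matrix with `classes` as dimnames.
#' @export
build_confusion <- function(decisions, truth, classes = NULL) {
  if (is.null(classes)) classes <- attr(decisions, "class_labels")
  if (is.null(classes)) classes <- sort(unique(c(decisions$decided, unlist(truth))))
  truth <- unlist(truth)
  missing <- setdiff(decisions$video_id, names(truth))
  if (length(missing)) {
    abort(sprintf("no truth label for video(s): %s",
                  paste(missing, collapse = ", ")), "slitflow_decision_error")
  }
  tt <- factor(truth[decisions$video_id], levels = classes)
  dd <- factor(decisions$decided, levels = classes)
  m <- table(truth = tt, decided = dd)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(truth = as.character(classes),
                         decided = as.character(classes)))
}

#' Video-level efficiency of a confusion matrix
#'
#' Overall accuracy: the trace divided by the total count. Kept at full
#' precision; use [format_efficiency()] for the rounded percentage display.
#'
#' @param confusion square count matrix.
#' @return Fraction in `[0, 1]`.
#' @export
efficiency <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) {
    abort("efficiency is undefined for an empty confusion matrix",
          "slitflow_decision_error")
  }
  sum(diag(confusion)) / total
}

#' Display an efficiency as the integer-rounded percentage
#' @param x fraction from [efficiency()].
#' @export
format_efficiency <- function(x) sprintf("%d%%", as.integer(round(100 * x)))

#' Per-video score profile of a decision set
#'
#' One row per video: the assigned class and the normalised score of the
#' winning class (for maximum-trustiness decisions), plus the true class —
#' the data behind a score-profile bar sketch of a cohort.
#'
#' @param decisions data frame from [decide_videos()].
#' @param truth named vector of true labels.
#' @export
score_profile <- function(decisions, truth) {
  truth <- unlist(truth)
  data.frame(video_id = decisions$video_id,
             assigned = decisions$decided,
             normalized_score = decisions$normalized_score,
             truth = unname(truth[decisions$video_id]),
             stringsAsFactors = FALSE)
}
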