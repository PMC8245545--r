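# Linear SVM models for the two-class (healthy vs unhealthy) and four-class
# (healthy vs SCD vs THAL vs HS) problems, with normalised per-class scores.

problem_classes <- function(problem = c("two_class", "four_class")) {
  problem <- match.arg(problem)
  if (problem == "two_class") 0:1 else 0:3
}

#' Map condition labels to class labels
#'
#' Two-class: healthy = 0, any RHHA subtype = 1. Four-class: healthy = 0,
#' SCD = 1, THAL = 2, HS = 3.
#'
#' @param condition character vector of conditions.
#' @param problem `"two_class"` or `"four_class"`.
#' @return Integer class labels.
#' @export
condition_to_label <- function(condition, problem = c("two_class", "four_class")) {
  problem <- match.arg(problem)
  if (problem == "two_class") {
    as.integer(condition != "healthy")
  } else {
    unname(c(healthy = 0L, SCD = 1L, THAL = 2L, HS = 3L)[condition])
  }
}

#' Train a linear SVM classifier (one-vs-all)
#'
#' Fits one linear-kernel support vector separator per class against the
#' rest (for the two-class problem this reduces to two mirrored separators)
#' on standardised features (centre/scale estimated from the training rows;
#' linear SVMs on raw activations are scale-sensitive). The linear weights
#' are extracted from the support vectors so prediction is a plain affine
#' map. Classes absent from the training data receive a -Inf-like bias so
#' their scores vanish. Deterministic: libsvm on fixed input has no
#' randomness at these settings.
#'
#' @param features a `feature_table` or numeric matrix.
#' @param labels integer class labels aligned with rows.
#' @param problem `"two_class"` or `"four_class"`.
#' @param cost SVM regularisation constant C.
#' @param class_weights `NULL` for unweighted hinge loss (default), or
#'   `"inverse"` for inverse-frequency class weighting.
#' @return An object of class `rbc_classifier` with per-class weight vectors
#'   `W`, biases `b`, standardisation parameters and score calibration tag.
#' @export
train_classifier <- function(features, labels,
                             problem = c("two_class", "four_class"),
                             cost = 1, class_weights = NULL) {
  problem <- match.arg(problem)
  x <- if (inherits(features, "feature_table")) features$matrix else features
  x <- as.matrix(x)
  if (nrow(x) != length(labels)) {
    abort("labels must align with feature rows", "slitflow_shape_error")
  }
  classes <- problem_classes(problem)
  if (!all(labels %in% classes)) {
    abort("labels outside the problem's class set", "slitflow_training_error")
  }
  if (length(unique(labels)) < 2L) {
    abort("training data contains a single class", "slitflow_training_error")
  }
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  z <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")

  d <- ncol(z)
  W <- matrix(0, d, length(classes),
              dimnames = list(NULL, paste0("class_", classes)))
  b <- stats::setNames(rep(-1e6, length(classes)), paste0("class_", classes))
  if (problem == "two_class") {
    # one separator, mirrored: the two-class problem is a single margin
    pos <- labels == 1L
    y <- factor(ifelse(pos, "pos", "rest"), levels = c("pos", "rest"))
    cw <- NULL
    if (identical(class_weights, "inverse")) {
      cw <- c(pos = length(y) / (2 * sum(pos)),
              rest = length(y) / (2 * sum(!pos)))
    }
    fit <- e1071::svm(z, y, kernel = "linear", cost = cost, scale = FALSE,
                      class.weights = cw)
    wk <- drop(t(fit$coefs) %*% fit$SV)
    bk <- -fit$rho
    dec <- z %*% wk + bk
    if (mean(dec[pos]) < mean(dec[!pos])) {
      wk <- -wk; bk <- -bk
    }
    W[, 2L] <- wk / 2; b[2L] <- bk / 2
    W[, 1L] <- -wk / 2; b[1L] <- -bk / 2
    return(structure(list(problem = problem, class_labels = classes, W = W,
                          b = b, center = center, scale = scale, cost = cost,
                          score_calibration = "softmax"),
                     class = "rbc_classifier"))
  }
  for (k in seq_along(classes)) {
    cls <- classes[k]
    pos <- labels == cls
    if (!any(pos) ) next                 # class absent: score stays ~0
    y <- factor(ifelse(pos, "pos", "rest"), levels = c("pos", "rest"))
    cw <- NULL
    if (identical(class_weights, "inverse")) {
      cw <- c(pos = length(y) / (2 * sum(pos)),
              rest = length(y) / (2 * sum(!pos)))
    }
    fit <- e1071::svm(z, y, kernel = "linear", cost = cost, scale = FALSE,
                      class.weights = cw)
    wk <- drop(t(fit$coefs) %*% fit$SV)
    bk <- -fit$rho
    dec <- z %*% wk + bk
    if (mean(dec[pos]) < mean(dec[!pos])) {   # orient: positive favours cls
      wk <- -wk; bk <- -bk
    }
    W[, k] <- wk
    b[k] <- bk
  }
  structure(list(problem = problem, class_labels = classes, W = W, b = b,
                 center = center, scale = scale, cost = cost,
                 score_calibration = "softmax"),
            class = "rbc_classifier")
}

#' @export
print.rbc_classifier <- function(x, ...) {
  cat(sprintf("rbc_classifier (%s): %d linear one-vs-all separators over %d features\n",
              x$problem, length(x$class_labels), nrow(x$W)))
  invisible(x)
}

#' Score ROIs with a trained classifier
#'
#' Decision values of the one-vs-all separators are mapped to normalised
#' per-class scores by a softmax (temperature 1), so each ROI's scores are
#' in `[0, 1]` and sum to one; the assigned label is the argmax with
#' deterministic tie-break towards the lowest class index. Softmax is
#' monotone in the decision values, so per-ROI score ranking equals
#' decision-value ranking.
#'
#' @param object an `rbc_classifier`.
#' @param features a `feature_table` or matrix with matching columns.
#' @param ... unused.
#' @return A `scored_predictions` data frame: `roi_id`, `video_id` (when
#'   available), `label`, and one `score_<class>` column per class.
#' @export
predict.rbc_classifier <- function(object, features, ...) {
  x <- if (inherits(features, "feature_table")) features$matrix else features
  x <- as.matrix(x)
  if (ncol(x) != nrow(object$W)) {
    abort(sprintf("feature dimensionality %d does not match model (%d)",
                  ncol(x), nrow(object$W)), "slitflow_shape_error")
  }
  z <- sweep(sweep(x, 2L, object$center, "-"), 2L, object$scale, "/")
  dec <- sweep(z %*% object$W, 2L, object$b, "+")
  scores <- softmax_rows(dec)
  lab <- object$class_labels[max.col(scores, ties.method = "first")]
  idx <- if (inherits(features, "feature_table")) features$roi_index else NULL
  out <- data.frame(
    roi_id = if (!is.null(idx)) idx$roi_id else sprintf("roi_%d", seq_len(nrow(x))),
    video_id = if (!is.null(idx) && "video_id" %in% names(idx)) idx$video_id
               else NA_character_,
    label = lab, stringsAsFactors = FALSE)
  sc <- as.data.frame(scores)
  names(sc) <- paste0("score_", object$class_labels)
  out <- cbind(out, sc)
  attr(out, "class_labels") <- object$class_labels
  class(out) <- c("scored_predictions", "data.frame")
  out
}

score_columns <- function(predictions) {
  grep("^score_", names(predictions), value = TRUE)
}

prediction_classes <- function(predictions) {
  cl <- attr(predictions, "class_labels")
  if (!is.null(cl)) return(cl)
  as.integer(sub("^score_", "", score_columns(predictions)))
}
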