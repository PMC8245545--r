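# Unsupervised elimination of features with small variation over the
# dataset, the pre-classification refining step.

#' Fit a low-variance elimination mask
#'
#' Unsupervised: only the feature matrix is consulted, never labels. In
#' `threshold` mode, columns whose sample variance (denominator n-1) exceeds
#' `value` are retained. In `target_factor` mode the variance threshold is
#' placed at the quantile that retains `ceiling(n_features / value)` columns
#' (the paper-scale CNN coding reduces 9216 columns by a factor of 50 this
#' way); variance ties are broken by keeping the lower column index.
#' Features are not standardised before selection: the filter acts on raw
#' variation.
#'
#' @param features a `feature_table` or numeric matrix with >= 2 rows. When
#'   used inside cross-validation, pass the training rows only.
#' @param mode `"target_factor"` or `"threshold"`.
#' @param value reduction factor (>= 1) or variance threshold (> 0 mode
#'   `threshold` accepts 0 to drop exactly-constant columns).
#' @return An object of class `selection_mask`: `retained` (logical),
#'   `threshold`, `reduction_factor`, `mode`, `value`, `backend_name`.
#' @export
fit_low_variance_mask <- function(features,
                                  mode = c("target_factor", "threshold"),
                                  value = 50) {
  mode <- match.arg(mode)
  x <- if (inherits(features, "feature_table")) features$matrix else features
  backend <- if (inherits(features, "feature_table")) features$backend_name
             else NA_character_
  if (nrow(x) < 2L) {
    abort("need at least 2 rows to estimate column variances",
          "slitflow_selection_error")
  }
  if (!is.numeric(value) || length(value) != 1L || value < 0 ||
      (mode == "target_factor" && value < 1)) {
    abort("invalid selection value", "slitflow_selection_error")
  }
  v <- col_variances(x)
  d <- length(v)
  if (all(v <= 0)) {
    abort("all features are constant; nothing can be retained",
          "slitflow_selection_error")
  }
  if (mode == "threshold") {
    retained <- v > value
    thr <- value
    if (!any(retained)) {
      abort("variance threshold would remove every feature",
            "slitflow_selection_error")
    }
  } else {
    k <- min(d, ceiling(d / value))
    ord <- order(-v, seq_len(d))      # ties keep the lower column index
    keep_idx <- sort(ord[seq_len(k)])
    retained <- rep(FALSE, d)
    retained[keep_idx] <- TRUE
    thr <- sort(v, decreasing = TRUE)[k]
  }
  structure(list(retained = retained, threshold = thr,
                 reduction_factor = d / sum(retained),
                 mode = mode, value = value, backend_name = backend),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("selection_mask: %d of %d features retained (factor %.2f, %s)\n",
              sum(x$retained), length(x$retained), x$reduction_factor, x$mode))
  invisible(x)
}

#' Apply a selection mask to a feature table
#'
#' Column subset; row alignment is unchanged, so a mask fitted on training
#' rows yields the identical column set on any other partition.
#'
#' @param features a `feature_table` (or matrix).
#' @param mask a `selection_mask` of matching length.
#' @export
apply_mask <- function(features, mask) {
  stopifnot(inherits(mask, "selection_mask"))
  x <- if (inherits(features, "feature_table")) features$matrix else features
  if (ncol(x) != length(mask$retained)) {
    abort(sprintf("mask length %d does not match %d feature columns",
                  length(mask$retained), ncol(x)), "slitflow_shape_error")
  }
  if (inherits(features, "feature_table")) {
    feature_table(x[, mask$retained, drop = FALSE], features$roi_index,
                  features$backend_name,
                  features$feature_names[mask$retained])
  } else {
    x[, mask$retained, drop = FALSE]
  }
}

#' Serialise a selection mask to JSON
#' @param mask a `selection_mask`.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  jsonlite::write_json(
    list(threshold = mask$threshold,
         retained_indices = which(mask$retained),
         n_features = length(mask$retained),
         mode = mask$mode, value = mask$value,
         backend_name = mask$backend_name),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
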