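# ROI feature coding: handcrafted shape descriptors or a pretrained-CNN
# pool5 layer, behind one pluggable backend interface.

.slitflow_cache <- new.env(parent = emptyenv())

#' Handcrafted descriptor names, in their frozen order
#' @export
handcrafted_feature_names <- function() {
  c("area", "perimeter", "circularity", "eccentricity", "solidity",
    paste0("hu", 1:7), "fg_mean", "fg_sd", "fg_skew", paste0("radial", 1:8))
}

# Hu's seven moment invariants from binary-mask pixel coordinates.
hu_moments <- function(coords) {
  x <- coords[, 2]; y <- coords[, 1]
  xb <- mean(x); yb <- mean(y)
  m00 <- nrow(coords)
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

# Eccentricity of the mask's equivalent ellipse (second central moments).
mask_eccentricity <- function(coords) {
  if (nrow(coords) < 3L) return(0)
  x <- coords[, 2]; y <- coords[, 1]
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

# 4-connected boundary pixel count.
mask_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- mask
  inner <- p[2:(h + 1), 2:(w + 1)]
  nb <- p[1:h, 2:(w + 1)] & p[3:(h + 2), 2:(w + 1)] &
    p[2:(h + 1), 1:w] & p[2:(h + 1), 3:(w + 2)]
  sum(inner & !nb)
}

# Convex-hull area of pixel coordinates with a half-pixel boundary
# correction so a solid component scores ~1.
hull_area <- function(coords) {
  if (nrow(coords) < 3L) return(nrow(coords))
  hidx <- grDevices::chull(coords[, 2], coords[, 1])
  hx <- coords[hidx, 2]; hy <- coords[hidx, 1]
  nh <- length(hx)
  a <- abs(sum(hx * hy[c(2:nh, 1)] - hx[c(2:nh, 1)] * hy)) / 2
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  a + per / 2 + 1
}

radial_bin_index <- function(size, n_bins = 8L) {
  key <- sprintf("radial_%d_%d", size, n_bins)
  if (!is.null(.slitflow_cache[[key]])) return(.slitflow_cache[[key]])
  ctr <- (size + 1) / 2
  d <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  breaks <- seq(0, size / 2, length.out = n_bins + 1L)
  idx <- findInterval(d, breaks, rightmost.closed = TRUE)
  idx[idx < 1L | idx > n_bins] <- NA_integer_
  .slitflow_cache[[key]] <- idx
  idx
}

#' Handcrafted shape and intensity descriptors for one ROI
#'
#' Deterministic fixed-order vector computed on an Otsu-thresholded mask of
#' the connected dark component nearest the crop centre: foreground area,
#' perimeter, circularity \eqn{4\pi A / P^2}, eccentricity, solidity, the
#' seven Hu moment invariants, mean/sd/skewness of the foreground gray
#' levels, and an 8-bin radial intensity profile around the crop centre.
#' Crops with no usable foreground (e.g. pure background) yield an all-zero
#' shape block and intensity statistics of the whole crop.
#'
#' @param img square grayscale matrix in `[0, 1]` (cells dark on a bright
#'   background).
#' @param min_area smallest component area (px) accepted as a cell.
#' @return Named numeric vector, names as [handcrafted_feature_names()].
#' @export
handcrafted_descriptors <- function(img, min_area = 9L) {
  if (!is.matrix(img) || nrow(img) != ncol(img)) {
    abort("ROI image must be a square matrix", "slitflow_shape_error")
  }
  size <- nrow(img)
  out <- stats::setNames(numeric(23L), handcrafted_feature_names())

  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  fg <- img < thr
  mask <- NULL
  # Otsu always splits; demand real foreground/background contrast so a
  # pure-noise crop is treated as blank rather than speckled
  if (any(fg) && !all(fg) &&
      mean(img[!fg]) - mean(img[fg]) >= 0.1) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
    areas <- tabulate(lab[lab > 0])
    comps <- which(areas >= min_area)
    if (length(comps)) {
      ctr <- (size + 1) / 2
      stats_c <- vapply(comps, function(cpt) {
        cc <- which(lab == cpt, arr.ind = TRUE)
        c(d2 = (mean(cc[, 1]) - ctr)^2 + (mean(cc[, 2]) - ctr)^2,
          mean_int = mean(img[lab == cpt]))
      }, numeric(2))
      # exact-zero regions are edge padding, not cells
      comps <- comps[stats_c["mean_int", ] >= 0.05]
      stats_c <- stats_c[, stats_c["mean_int", ] >= 0.05, drop = FALSE]
      if (length(comps)) {
        # the cell is the largest dark component; centrality breaks ties
        ord <- order(-areas[comps], stats_c["d2", ])
        mask <- lab == comps[ord[1L]]
      }
    }
  }

  if (!is.null(mask)) {
    coords <- which(mask, arr.ind = TRUE)
    area <- nrow(coords)
    per <- mask_perimeter(mask)
    out["area"] <- area
    out["perimeter"] <- per
    out["circularity"] <- if (per > 0) 4 * pi * area / per^2 else 0
    out["eccentricity"] <- mask_eccentricity(coords)
    out["solidity"] <- area / max(hull_area(coords), 1)
    out[paste0("hu", 1:7)] <- hu_moments(coords)
    vals <- img[mask]
    out["fg_mean"] <- mean(vals)
    s <- if (length(vals) > 1L) stats::sd(vals) else 0
    out["fg_sd"] <- s
    out["fg_skew"] <- if (s > 0) mean((vals - mean(vals))^3) / s^3 else 0
  } else {
    vals <- as.numeric(img)
    out["fg_mean"] <- mean(vals)
    s <- stats::sd(vals)
    out["fg_sd"] <- s
    out["fg_skew"] <- if (s > 0) mean((vals - mean(vals))^3) / s^3 else 0
  }

  bins <- radial_bin_index(size)
  means <- tapply(as.numeric(img), bins, mean)
  out[paste0("radial", 1:8)] <- as.numeric(means[as.character(1:8)])
  out[is.na(out)] <- 0
  out
}

#' Declare a feature-coding backend
#'
#' Two backends share one interface: `"handcrafted"` (deterministic shape
#' descriptors, no external weights, the offline default) and `"cnn"` (the
#' pool5 activations of a pretrained AlexNet-geometry network, loaded from a
#' local weights file; nothing is ever downloaded and the network is never
#' fine-tuned).
#'
#' @param name `"handcrafted"` or `"cnn"`.
#' @param weights_file for the CNN backend, path to an RDS weights file (see
#'   [synthetic_cnn_weights()] for the format).
#' @param input_size CNN input side in pixels.
#' @return An object of class `feature_backend`.
#' @export
feature_backend <- function(name = c("handcrafted", "cnn"),
                            weights_file = NULL, input_size = 224L) {
  name <- match.arg(name)
  structure(list(name = name, weights_file = weights_file,
                 input_size = as.integer(input_size)),
            class = "feature_backend")
}

#' Code ROIs into a feature table
#'
#' Applies the backend to every ROI crop; identical images map to identical
#' rows. The CNN backend replicates the grayscale crop to three channels,
#' bilinearly resizes it to the network input, and reads the flattened
#' third-max-pooling (pool5) activations; when its weights file is absent a
#' capability error is raised that points at the handcrafted backend.
#'
#' @param rois a `roi_set`.
#' @param backend a [feature_backend()] (or its name as a string).
#' @return An object of class `feature_table`: `$matrix`
#'   (`n_rois x n_features`), `$roi_index` (the ROI info data frame),
#'   `$backend_name`, `$feature_names`.
#' @export
extract_features <- function(rois, backend = feature_backend("handcrafted")) {
  stopifnot(inherits(rois, "roi_set"))
  if (is.character(backend)) backend <- feature_backend(backend)
  n <- nrow(rois$info)
  if (backend$name == "handcrafted") {
    fn <- handcrafted_feature_names()
    mat <- matrix(0, n, length(fn), dimnames = list(rois$info$roi_id, fn))
    for (i in seq_len(n)) mat[i, ] <- handcrafted_descriptors(rois$images[, , i])
  } else {
    weights <- load_cnn_weights(backend$weights_file)
    d <- alexnet_feature_dim(backend$input_size)
    fn <- paste0("pool5_", seq_len(d))
    mat <- matrix(0, n, d, dimnames = list(rois$info$roi_id, fn))
    for (i in seq_len(n)) {
      mat[i, ] <- cnn_pool5_features(rois$images[, , i], weights,
                                     backend$input_size)
    }
  }
  feature_table(mat, rois$info, backend$name, fn)
}

#' Construct a feature table
#' @param matrix numeric `n_rois x n_features` matrix, no missing values.
#' @param roi_index data frame aligned with the rows.
#' @param backend_name provenance string.
#' @param feature_names optional column names.
#' @export
feature_table <- function(matrix, roi_index, backend_name,
                          feature_names = colnames(matrix)) {
  if (nrow(matrix) != nrow(roi_index)) {
    abort("feature rows must align with the ROI index", "slitflow_shape_error")
  }
  if (anyNA(matrix)) abort("feature table contains missing values",
                           "slitflow_shape_error")
  structure(list(matrix = matrix, roi_index = roi_index,
                 backend_name = backend_name, feature_names = feature_names),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d ROIs x %d features (backend '%s')\n",
              nrow(x$matrix), ncol(x$matrix), x$backend_name))
  invisible(x)
}

#' Row subset of a feature table
#' @param features a `feature_table`.
#' @param idx row indices (integer or logical).
#' @export
subset_feature_rows <- function(features, idx) {
  feature_table(features$matrix[idx, , drop = FALSE],
                features$roi_index[idx, , drop = FALSE],
                features$backend_name, features$feature_names)
}

#' Persist / load a feature table as CSV
#'
#' Index columns (`roi_id`, `video_id`, `frame`, `side`) precede the feature
#' columns; backend provenance travels in a `backend` column.
#' @param features a `feature_table`.
#' @param path CSV path.
#' @export
write_feature_csv <- function(features, path) {
  idx <- features$roi_index[, intersect(c("roi_id", "video_id", "frame", "side"),
                                        names(features$roi_index)), drop = FALSE]
  utils::write.csv(cbind(idx, backend = features$backend_name,
                         as.data.frame(features$matrix)),
                   path, row.names = FALSE)
  invisible(path)
}
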