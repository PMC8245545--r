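# Circular Hough transform detection and fixed-size ROI extraction.

sobel_gradients <- function(m) {
  p <- pad_replicate1(m)
  h <- nrow(m); w <- ncol(m)
  sh <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
    (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)) -
    (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# 3x3 neighbourhood maximum (replicated borders), for local-peak picking.
local_max3 <- function(m) {
  p <- pad_replicate1(m)
  h <- nrow(m); w <- ncol(m)
  sh <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  out <- sh(-1L, -1L)
  for (d in list(c(-1L, 0L), c(-1L, 1L), c(0L, -1L), c(0L, 0L), c(0L, 1L),
                 c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
    out <- pmax(out, sh(d[1], d[2]))
  }
  out
}

#' Detect quasi-circular cells in one frame
#'
#' Circular Hough transform with gradient-direction voting: Sobel edge
#' pixels vote for candidate centres at every radius in
#' `r_min:r_max` along both gradient directions; the accumulator is smoothed
#' with a 3x3 box, normalised by the circle circumference, and local maxima
#' above `sensitivity` are kept. Non-maximum suppression removes detections
#' whose centres lie closer than `nms_dist`. An empty result is valid (e.g.
#' a blank frame).
#'
#' @param frame numeric matrix (grayscale, `[0, 1]`).
#' @param r_min,r_max inclusive integer radius bounds, `r_min <= r_max`.
#' @param sensitivity accumulator score threshold in `[0, 1]`-ish units
#'   (1 corresponds to a full circle of strong edges).
#' @param edge_quantile quantile of the gradient magnitude above which pixels
#'   vote.
#' @param min_edge_mag absolute gradient-magnitude floor, so pure-noise
#'   frames contribute no votes.
#' @param nms_dist minimum centre-to-centre distance between detections;
#'   defaults to `r_min`.
#' @return A data frame with columns `row`, `col`, `radius`,
#'   `score`, ordered by descending score (ties by row then col).
#' @export
detect_cells <- function(frame, r_min, r_max, sensitivity = 0.3,
                         edge_quantile = 0.9, min_edge_mag = 0.2,
                         nms_dist = r_min) {
  if (!is.matrix(frame)) abort("frame must be a 2-D matrix", "slitflow_format_error")
  if (r_min > r_max || r_min < 1) {
    abort("need 1 <= r_min <= r_max", "slitflow_config_error")
  }
  empty <- data.frame(row = numeric(), col = numeric(), radius = numeric(),
                      score = numeric())
  h <- nrow(frame); w <- ncol(frame)
  g <- sobel_gradients(frame)
  thr <- max(stats::quantile(g$mag, edge_quantile, names = FALSE), min_edge_mag)
  sel <- which(g$mag > thr)
  if (length(sel) == 0L) return(empty)
  ii <- ((sel - 1L) %% h) + 1L
  jj <- ((sel - 1L) %/% h) + 1L
  uy <- g$gy[sel] / g$mag[sel]
  ux <- g$gx[sel] / g$mag[sel]
  radii <- seq(as.integer(round(r_min)), as.integer(round(r_max)))
  nr <- length(radii)

  # cells are dark on a bright background: the intensity gradient at a cell
  # edge points outward, so candidate centres lie against the gradient
  votes <- integer(0)
  for (k in seq_len(nr)) {
    r <- radii[k]
    ci <- as.integer(round(ii - r * uy))
    cj <- as.integer(round(jj - r * ux))
    ok <- ci >= 1L & ci <= h & cj >= 1L & cj <= w
    if (any(ok)) {
      votes <- c(votes, ci[ok] + (cj[ok] - 1L) * h + (k - 1L) * h * w)
    }
  }
  if (length(votes) == 0L) return(empty)
  acc <- array(tabulate(votes, nbins = h * w * nr), dim = c(h, w, nr))

  # per-radius smoothed, circumference-normalised score; best radius per px
  best_score <- matrix(-Inf, h, w)
  best_r <- matrix(radii[1], h, w)
  for (k in seq_len(nr)) {
    s <- box_sum3(acc[, , k]) / (2 * pi * radii[k])
    upd <- s > best_score
    best_score[upd] <- s[upd]
    best_r[upd] <- radii[k]
  }

  peaks <- best_score >= sensitivity & best_score >= local_max3(best_score)
  cand <- which(peaks, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  sc <- best_score[peaks]
  ord <- order(-sc, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  sc <- sc[ord]

  # radius-aware non-maximum suppression: a weaker peak is dropped when it
  # lies within a kept detection's radius, or when its own circle reaches a
  # kept centre (ghost rings around a strong cell), floored at nms_dist
  keep <- logical(nrow(cand))
  kr <- numeric(0); kc <- numeric(0); ks <- numeric(0)
  for (t in seq_len(nrow(cand))) {
    cr <- best_r[cand[t, , drop = FALSE]]
    if (length(kr) == 0L ||
        all((kr - cand[t, 1])^2 + (kc - cand[t, 2])^2 >=
              pmax(nms_dist, ks, cr)^2)) {
      keep[t] <- TRUE
      kr <- c(kr, cand[t, 1]); kc <- c(kc, cand[t, 2])
      ks <- c(ks, cr)
    }
  }
  data.frame(row = cand[keep, 1], col = cand[keep, 2],
             radius = best_r[cand[keep, , drop = FALSE]],
             score = sc[keep], row.names = NULL)
}

#' Detect cells in every frame of a video
#'
#' With `background_subtract = TRUE` (the default) a per-pixel temporal
#' median over up to 50 sampled frames is removed from every frame before
#' edge detection, so static structures (the slit-barrier band, debris)
#' contribute no Hough votes while moving cells are untouched — standard
#' practice for fixed-stage time-lapse recordings.
#'
#' @param video a `video_record`.
#' @param r_min,r_max,sensitivity,... passed to [detect_cells()].
#' @param background_subtract remove the static temporal-median background
#'   before detection.
#' @return A data frame of detections with a `frame_index` column, ordered by
#'   frame then descending score.
#' @export
detect_video <- function(video, r_min, r_max, sensitivity = 0.3,
                         background_subtract = TRUE, ...) {
  stopifnot(inherits(video, "video_record"))
  frames <- video$frames
  if (background_subtract && length(frames) >= 3L) {
    take <- unique(round(seq(1, length(frames), length.out = min(length(frames), 50))))
    stack <- array(unlist(frames[take], use.names = FALSE),
                   dim = c(dim(frames[[1]]), length(take)))
    bg <- apply(stack, c(1, 2), stats::median)
    frames <- lapply(frames, function(f) clamp01(f - bg + .bg_level))
  }
  per <- lapply(seq_along(frames), function(f) {
    d <- detect_cells(frames[[f]], r_min, r_max, sensitivity, ...)
    if (nrow(d)) cbind(frame_index = f, d) else NULL
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) == 0L) {
    return(data.frame(frame_index = integer(), row = numeric(),
                      col = numeric(), radius = numeric(), score = numeric()))
  }
  do.call(rbind, per)
}

#' Hough radius bounds from a configured cell radius
#'
#' RBC size is tightly distributed, so the search range is the configured
#' mean projected radius +/- 50%.
#'
#' @param cell_radius_mean mean projected cell radius in pixels.
#' @return Integer vector `c(r_min, r_max)`.
#' @export
hough_radii <- function(cell_radius_mean = 8) {
  c(max(2L, as.integer(round(0.5 * cell_radius_mean))),
    as.integer(round(1.5 * cell_radius_mean)))
}

#' Extract fixed-size ROIs around detections
#'
#' One square crop of side `roi_size` per detection; crops at frame edges are
#' zero-padded to full size. Each ROI is tagged `side = "after"` iff its
#' centre column exceeds `barrier_x`, else `"before"`.
#'
#' @param video a `video_record`.
#' @param detections data frame from [detect_video()] (needs `frame_index`,
#'   `row`, `col`, `score`).
#' @param roi_size positive even crop side, px.
#' @param barrier_x barrier column in the video's coordinates.
#' @return An object of class `roi_set`: `$images` (array
#'   `roi_size x roi_size x n`) and `$info` (data frame with `roi_id`,
#'   `video_id`, `frame`, `row`, `col`, `radius`, `side`, `score`).
#' @export
extract_rois <- function(video, detections, roi_size = 32L,
                         barrier_x = video$barrier_x) {
  stopifnot(inherits(video, "video_record"))
  if (!is_count(roi_size) || roi_size < 2 || roi_size %% 2 != 0) {
    abort("roi_size must be a positive even integer", "slitflow_config_error")
  }
  if (is.null(barrier_x)) {
    abort("barrier_x is required to assign ROI sides", "slitflow_config_error")
  }
  n <- nrow(detections)
  half <- roi_size / 2L
  imgs <- array(0, dim = c(roi_size, roi_size, max(n, 0L)))
  if (n > 0L) {
    nfr <- length(video$frames)
    if (any(detections$frame_index < 1 | detections$frame_index > nfr)) {
      abort("detections reference frames outside the video", "slitflow_format_error")
    }
    h <- nrow(video$frames[[1]]); w <- ncol(video$frames[[1]])
    for (t in seq_len(n)) {
      rr <- as.integer(round(detections$row[t]))
      cc <- as.integer(round(detections$col[t]))
      rows <- (rr - half + 1L):(rr + half)
      cols <- (cc - half + 1L):(cc + half)
      vr <- rows >= 1L & rows <= h
      vc <- cols >= 1L & cols <= w
      crop <- matrix(0, roi_size, roi_size)
      if (any(vr) && any(vc)) {
        crop[vr, vc] <- video$frames[[detections$frame_index[t]]][rows[vr], cols[vc]]
      }
      imgs[, , t] <- crop
    }
  }
  info <- data.frame(
    roi_id = if (n > 0L) sprintf("%s_f%04d_r%03d_c%03d_%02d", video$video_id,
                                 detections$frame_index,
                                 as.integer(round(detections$row)),
                                 as.integer(round(detections$col)),
                                 seq_len(n)) else character(),
    video_id = rep(video$video_id, n),
    frame = if (n > 0L) detections$frame_index else integer(),
    row = if (n > 0L) as.integer(round(detections$row)) else integer(),
    col = if (n > 0L) as.integer(round(detections$col)) else integer(),
    radius = if (n > 0L) detections$radius else numeric(),
    side = if (n > 0L) ifelse(detections$col > barrier_x, "after", "before")
           else character(),
    score = if (n > 0L) detections$score else numeric(),
    stringsAsFactors = FALSE)
  structure(list(images = imgs, info = info, roi_size = as.integer(roi_size)),
            class = "roi_set")
}

#' Filter ROIs by barrier side and detection score
#'
#' The default analysis keeps only post-barrier ROIs, where cells have had
#' the chance to recover (or not) their resting shape.
#'
#' @param rois a `roi_set`.
#' @param side `"after"`, `"before"` or `"both"`.
#' @param min_score minimum detection score.
#' @return An order-preserving `roi_set` subset.
#' @export
filter_rois <- function(rois, side = c("after", "before", "both"),
                        min_score = 0) {
  stopifnot(inherits(rois, "roi_set"))
  side <- match.arg(side)
  keep <- rois$info$score >= min_score
  if (side != "both") keep <- keep & rois$info$side == side
  subset_rois(rois, which(keep))
}

#' Index-based subset of a ROI set
#' @param rois a `roi_set`.
#' @param idx integer indices into the ROI list.
#' @export
subset_rois <- function(rois, idx) {
  structure(list(images = rois$images[, , idx, drop = FALSE],
                 info = rois$info[idx, , drop = FALSE],
                 roi_size = rois$roi_size),
            class = "roi_set")
}

#' Combine ROI sets from several videos
#' @param roi_list list of `roi_set` objects with equal `roi_size`.
#' @return One `roi_set`.
#' @export
bind_rois <- function(roi_list) {
  roi_list <- roi_list[vapply(roi_list, function(r) nrow(r$info) > 0, logical(1))]
  if (length(roi_list) == 0L) abort("no ROIs to combine", "slitflow_format_error")
  sz <- unique(vapply(roi_list, `[[`, integer(1), "roi_size"))
  if (length(sz) != 1L) abort("roi_size differs across sets", "slitflow_shape_error")
  imgs <- array(unlist(lapply(roi_list, `[[`, "images"), use.names = FALSE),
                dim = c(sz, sz, sum(vapply(roi_list, function(r) nrow(r$info),
                                           integer(1)))))
  info <- do.call(rbind, lapply(roi_list, `[[`, "info"))
  rownames(info) <- NULL
  structure(list(images = imgs, info = info, roi_size = sz), class = "roi_set")
}

#' Match detections to ground-truth cell positions
#'
#' Greedy nearest-centre assignment per frame between detections and truth
#' appearances, used to score detection quality on synthetic videos. Truth
#' appearances are eligible when fully inside the frame, not overlap-marked,
#' and compact (true eccentricity below `max_ecc`): strongly elongated
#' in-slit appearances are weak circular-Hough responders by design and are
#' not part of the detection population.
#'
#' @param detections data frame from [detect_video()].
#' @param truth a `ground_truth` (in the same coordinates as `detections`).
#' @param frame_dim `c(height, width)` of the frames the detections came from.
#' @param max_dist matching radius in pixels.
#' @param max_ecc eligibility bound on true eccentricity.
#' @return A list with `recall`, `mean_center_error`, `n_eligible`,
#'   `n_matched`.
#' @export
evaluate_detection <- function(detections, truth, frame_dim, max_dist = 2,
                               max_ecc = 0.6) {
  tr <- truth$trajectory
  margin <- if (nrow(truth$cells)) max(truth$cells$radius) else 0
  elig <- tr[tr$col >= 1 + margin & tr$col <= frame_dim[2] - margin &
               tr$row >= 1 + margin & tr$row <= frame_dim[1] - margin &
               !tr$overlapping & tr$ecc <= max_ecc, , drop = FALSE]
  if (nrow(elig) == 0L) {
    return(list(recall = NA_real_, mean_center_error = NA_real_,
                n_eligible = 0L, n_matched = 0L))
  }
  matched <- 0L
  err <- numeric(0)
  for (f in unique(elig$frame)) {
    tf <- elig[elig$frame == f, , drop = FALSE]
    df <- detections[detections$frame_index == f, , drop = FALSE]
    if (nrow(df) == 0L) next
    used <- logical(nrow(df))
    for (t in seq_len(nrow(tf))) {
      d2 <- (df$row - tf$row[t])^2 + (df$col - tf$col[t])^2
      d2[used] <- Inf
      j <- which.min(d2)
      if (length(j) && d2[j] <= max_dist^2) {
        matched <- matched + 1L
        err <- c(err, sqrt(d2[j]))
        used[j] <- TRUE
      }
    }
  }
  list(recall = matched / nrow(elig),
       mean_center_error = if (length(err)) mean(err) else NA_real_,
       n_eligible = nrow(elig), n_matched = matched)
}
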