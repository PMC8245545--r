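#' Construct a video record
#'
#' A `video_record` holds an ordered list of grayscale frames (matrices in
#' `[0, 1]`, all the same shape) plus acquisition metadata.
#'
#' @param frames list of numeric matrices.
#' @param video_id identifier string.
#' @param fps frames per second, > 0.
#' @param condition optional class label.
#' @param barrier_x optional column index of the slit-barrier band centre.
#' @param source_path optional provenance path.
#' @return An object of class `video_record`.
#' @export
video_record <- function(frames, video_id = "video", fps = 85,
                         condition = NULL, barrier_x = NULL,
                         source_path = NA_character_) {
  if (!is.list(frames) || length(frames) == 0L) {
    abort("frames must be a non-empty list of matrices", "slitflow_format_error")
  }
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    abort(sprintf("frame %d has a different shape from frame 1", bad),
          "slitflow_format_error")
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    abort("fps must be positive", "slitflow_format_error")
  }
  structure(list(frames = frames, video_id = video_id, fps = fps,
                 condition = condition, barrier_x = barrier_x,
                 source_path = source_path),
            class = "video_record")
}

#' @export
print.video_record <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("video_record '%s': %d frames of %dx%d @ %g fps%s%s\n",
              x$video_id, length(x$frames), d[1], d[2], x$fps,
              if (!is.null(x$condition)) paste0(", condition=", x$condition) else "",
              if (!is.null(x$barrier_x)) paste0(", barrier_x=", x$barrier_x) else ""))
  invisible(x)
}

#' Number of frames in a video record
#' @param video a `video_record`.
#' @export
n_frames <- function(video) length(video$frames)

video_metadata <- function(video) {
  list(video_id = video$video_id, fps = video$fps,
       condition = video$condition, barrier_x = video$barrier_x,
       n_frames = length(video$frames))
}

sidecar_path <- function(path) {
  if (dir.exists(path)) file.path(path, "metadata.json")
  else paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a video as a multi-page TIFF or a directory of PNG frames
#'
#' Lossless formats only: frames produced by [generate_video()] are quantised
#' to 8-bit levels and round-trip exactly. A sidecar metadata JSON
#' (`<stem>.json` next to a TIFF, `metadata.json` inside a PNG directory)
#' records video id, fps, condition and barrier position.
#'
#' @param video a `video_record`.
#' @param path output path; `*.tif`/`*.tiff` writes a multi-page TIFF, any
#'   other path is treated as a directory of numbered PNG frames.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "video_record"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tiff::writeTIFF(video$frames, path, bits.per.sample = 8L,
                    compression = "none")
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(video$frames)) {
      png::writePNG(video$frames[[i]],
                    file.path(path, sprintf("frame_%05d.png", i)))
    }
  }
  jsonlite::write_json(video_metadata(video), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_one_frame <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
  else tiff::readTIFF(f)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Read a video from a multi-page TIFF or a directory of frames
#'
#' Accepts a multi-page TIFF stack or a directory of lexicographically
#' ordered PNG/TIFF frames. Sidecar metadata JSON written by [write_video()]
#' is loaded when present. AVI containers are not readable here; convert to
#' TIFF or PNG frames first.
#'
#' @param path file or directory.
#' @return A `video_record`.
#' @export
read_video <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      abort(sprintf("no PNG/TIFF frames found in directory '%s'", path),
            "slitflow_format_error")
    }
    frames <- lapply(files, read_one_frame)
    dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
    if (length(bad)) {
      abort(sprintf("frame '%s' has a mismatched shape", basename(files[bad[1]])),
            "slitflow_format_error")
    }
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) {
      abort(sprintf("file '%s' does not exist", path), "slitflow_format_error")
    }
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    frames <- lapply(frames, function(f) if (length(dim(f)) == 3L) f[, , 1L] else f)
  } else if (grepl("\\.avi$", path, ignore.case = TRUE)) {
    abort("AVI reading is not supported; convert the recording to a multi-page TIFF or PNG frames",
          "slitflow_format_error")
  } else {
    abort(sprintf("unreadable video path '%s'", path), "slitflow_format_error")
  }
  meta_file <- sidecar_path(path)
  meta <- if (file.exists(meta_file)) {
    jsonlite::read_json(meta_file, simplifyVector = TRUE)
  } else list()
  video_record(frames,
               video_id = meta$video_id %||% basename(tools::file_path_sans_ext(path)),
               fps = meta$fps %||% 85,
               condition = meta$condition,
               barrier_x = meta$barrier_x,
               source_path = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crop a video to the region around the slit barrier
#'
#' Keeps columns `[barrier_x - half_width, barrier_x + half_width]`
#' (inclusive, 1-based) and remaps `barrier_x` into the cropped coordinates.
#' A window extending past the frame is clipped with a warning. The applied
#' left offset is stored in the `col_offset` field so ground-truth
#' coordinates can be shifted with [shift_truth()].
#'
#' @param video a `video_record` with known `barrier_x` (estimated via
#'   [estimate_barrier_x()] when absent).
#' @param half_width half-width of the retained column window in pixels;
#'   the default, 72 px, spans several relaxation lengths past the band.
#' @return The cropped `video_record`.
#' @export
crop_to_barrier_region <- function(video, half_width = 48L) {
  stopifnot(inherits(video, "video_record"))
  if (!is_count(half_width) || half_width < 1) {
    abort("half_width must be a positive integer", "slitflow_config_error")
  }
  bx <- video$barrier_x
  if (is.null(bx)) bx <- estimate_barrier_x(video)
  w <- ncol(video$frames[[1]])
  lo <- bx - half_width
  hi <- bx + half_width
  if (lo < 1 || hi > w) {
    warning(sprintf("crop window [%d, %d] clipped to frame bounds [1, %d]",
                    lo, hi, w))
    lo <- max(1L, lo); hi <- min(w, hi)
  }
  out <- video
  out$frames <- lapply(video$frames, function(f) f[, lo:hi, drop = FALSE])
  out$barrier_x <- bx - lo + 1L
  out$col_offset <- (video$col_offset %||% 0L) + lo - 1L
  out
}

#' Estimate the slit-barrier column from the frames
#'
#' The barrier's micro-constrictions are the darkest persistent vertical
#' structure, so the estimate is the minimiser of the temporal-mean intensity
#' profile smoothed along columns. Deterministic; raises an estimation error
#' when no persistent vertical structure is present (flat profile).
#'
#' @param video a `video_record` with at least one frame.
#' @param smooth_width running-mean window (columns) applied to the profile.
#' @param min_contrast minimum smoothed-profile range below which the frame
#'   is declared barrier-free.
#' @return Column index (1-based) of the barrier centre.
#' @export
estimate_barrier_x <- function(video, smooth_width = 4L, min_contrast = 0.05) {
  stopifnot(inherits(video, "video_record"))
  nf <- length(video$frames)
  take <- unique(round(seq(1, nf, length.out = min(nf, 50))))
  tm <- Reduce(`+`, video$frames[take]) / length(take)
  p <- colMeans(tm)
  k <- smooth_width
  pad <- c(rep(p[1], k), p, rep(p[length(p)], k))
  sm <- stats::filter(pad, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
  sm <- as.numeric(sm)[(k + 1):(k + length(p))]
  if (max(sm) - min(sm) < min_contrast) {
    abort("no persistent vertical structure found; cannot locate the slit barrier",
          "slitflow_estimation_error")
  }
  which.min(sm)
}
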