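# Shared fixtures. Heavy cohort runs are memoised so several test files can
# reuse one rendered cohort.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(frame_size = c(64L, 160L), n_frames = 30L, n_cells = 4L,
                   seed = 123L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# Draw one filled ellipse (optionally rotated) on a bright background.
render_ellipse_frame <- function(size = 64L, cy = 32, cx = 32, a = 10, b = 10,
                                 depth = 0.4, bg = 0.85, theta = 0) {
  m <- matrix(bg, size, size)
  ys <- seq_len(size) - cy
  xs <- seq_len(size) - cx
  ct <- cos(theta); st <- sin(theta)
  for (i in seq_len(size)) {
    xr <- xs * ct + ys[i] * st
    yr <- -xs * st + ys[i] * ct
    d <- sqrt((xr / a)^2 + (yr / b)^2)
    m[i, ] <- m[i, ] - depth * pmin(1, pmax(0, (1 - d) * min(a, b) + 0.5))
  }
  m
}

# Random scored-prediction sets for decision-rule property tests.
random_predictions <- function(n, classes = 0:1, video_id = "v") {
  k <- length(classes)
  sc <- matrix(stats::runif(n * k), n, k)
  sc <- sc / rowSums(sc)
  out <- data.frame(roi_id = sprintf("%s_%03d", video_id, seq_len(n)),
                    video_id = video_id,
                    label = classes[max.col(sc, ties.method = "first")],
                    stringsAsFactors = FALSE)
  scdf <- as.data.frame(sc)
  names(scdf) <- paste0("score_", classes)
  out <- cbind(out, scdf)
  attr(out, "class_labels") <- classes
  class(out) <- c("scored_predictions", "data.frame")
  out
}

# The strongly separated 12-video end-to-end cohort (shared with the
# acceptance checks); computed once.
e2e_report <- function(seed = 20260925L) {
  memo(paste0("e2e_", seed), {
    cfg <- pipeline_config(
      counts = c(healthy = 6, SCD = 2, THAL = 2, HS = 2),
      video = list(n_frames = 120L, n_cells = 10L),
      abnormal_fraction = c(healthy = 0, SCD = 1, THAL = 1, HS = 1),
      problem = "two_class", seed = seed)
    run_pipeline(cfg)
  })
}
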