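test_that("a blank noisy frame yields no detections", {
  set.seed(4)
  frame <- 0.85 + matrix(rnorm(96 * 96, 0, 0.02), 96, 96)
  d <- detect_cells(pmin(pmax(frame, 0), 1), 5, 12)
  expect_equal(nrow(d), 0L)
})

test_that("well-separated disks are each found within 2 px", {
  set.seed(8)
  frame <- matrix(0.85, 96, 96)
  centers <- cbind(row = c(20, 50, 78), col = c(25, 70, 30))
  for (i in 1:3) {
    frame <- frame - 0.4 * pmin(1, pmax(0, (8 - sqrt(
      outer((seq_len(96) - centers[i, 1])^2,
            (seq_len(96) - centers[i, 2])^2, "+"))) + 0.5))
  }
  frame <- pmin(pmax(frame + matrix(rnorm(96 * 96, 0, 0.02), 96, 96), 0), 1)
  d <- detect_cells(frame, 5, 12)
  expect_equal(nrow(d), 3L)
  for (i in 1:3) {
    err <- min(sqrt((d$row - centers[i, 1])^2 + (d$col - centers[i, 2])^2))
    expect_lte(err, 2)
  }
  expect_true(all(d$radius >= 5 & d$radius <= 12))
})

test_that("near-coincident disks collapse to one detection after suppression", {
  frame <- matrix(0.85, 64, 64)
  for (cc in c(30, 34)) {   # centres 4 px apart = 0.5 * r_min for r_min = 8
    frame <- frame - 0.4 * pmin(1, pmax(0, (8 - sqrt(
      outer((seq_len(64) - 32)^2, (seq_len(64) - cc)^2, "+"))) + 0.5))
  }
  d <- detect_cells(frame, 8, 10)
  expect_equal(nrow(d), 1L)
})

test_that("detections are ordered by score with deterministic tie-break", {
  g <- generate_video(tiny_config(n_frames = 6L))
  d <- detect_video(g$video, 4, 12)
  per_frame <- split(d$score, d$frame_index)
  expect_true(all(vapply(per_frame, function(s) all(diff(s) <= 0), logical(1))))
})

test_that("detection recall and centre error hold on a synthetic video", {
  g <- generate_video(synthetic_config(n_frames = 60L, n_cells = 6L,
                                       condition = "healthy", seed = 31L))
  vc <- crop_to_barrier_region(g$video, 72L)
  ts <- shift_truth(g$truth, vc$col_offset)
  det <- detect_video(vc, 4, 12)
  q <- evaluate_detection(det, ts, dim(vc$frames[[1]]))
  expect_gte(q$recall, 0.95)
  expect_lte(q$mean_center_error, 2)
})

test_that("ROI extraction crops, pads, and assigns barrier sides", {
  g <- generate_video(tiny_config(n_frames = 4L))
  v <- g$video
  det <- data.frame(frame_index = c(1L, 1L, 2L),
                    row = c(32, 3, 40), col = c(80, 4, 100),
                    radius = 8, score = 1)
  rois <- extract_rois(v, det, roi_size = 32L, barrier_x = v$barrier_x)
  expect_equal(dim(rois$images), c(32L, 32L, 3L))
  # interior crop equals the frame block
  expect_identical(rois$images[, , 1], v$frames[[1]][17:48, 65:96])
  # corner crop is zero-padded yet full size: rows above the frame are 0
  expect_true(all(rois$images[1:13, , 2] == 0))
  expect_true(any(rois$images[, , 2] > 0))
  expect_equal(rois$info$side, ifelse(det$col > v$barrier_x, "after", "before"))
  # no ROI is called 'before' with a centre past the barrier
  expect_false(any(rois$info$side == "before" & rois$info$col > v$barrier_x))
  expect_error(extract_rois(v, det, roi_size = 31L),
               class = "slitflow_config_error")
})

test_that("re-extracting at a stored centre reproduces the crop", {
  g <- generate_video(tiny_config(n_frames = 5L, n_cells = 3L))
  v <- g$video
  det <- detect_video(v, 4, 12)
  rois <- extract_rois(v, det, 32L, v$barrier_x)
  i <- which(rois$info$frame == rois$info$frame[1])[1]
  again <- extract_rois(v, data.frame(frame_index = rois$info$frame[i],
                                      row = rois$info$row[i],
                                      col = rois$info$col[i],
                                      radius = rois$info$radius[i],
                                      score = rois$info$score[i]),
                        32L, v$barrier_x)
  expect_identical(again$images[, , 1], rois$images[, , i])
})

test_that("ROI filtering is order-preserving by side and score", {
  g <- generate_video(tiny_config(n_frames = 6L, n_cells = 4L))
  det <- detect_video(g$video, 4, 12)
  rois <- extract_rois(g$video, det, 32L, g$video$barrier_x)
  af <- filter_rois(rois, "after")
  expect_true(all(af$info$side == "after"))
  expect_false(is.unsorted(match(af$info$roi_id, rois$info$roi_id)))
  expect_equal(nrow(filter_rois(rois, "both", min_score = 0)$info),
               nrow(rois$info))
  hi <- filter_rois(rois, "both", min_score = 1)
  expect_true(all(hi$info$score >= 1))
})
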