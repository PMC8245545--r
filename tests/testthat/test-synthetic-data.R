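test_that("configuration validation rejects impossible videos", {
  expect_error(synthetic_config(abnormal_fraction = 1.5),
               class = "slitflow_config_error")
  expect_error(synthetic_config(abnormal_fraction = -0.1),
               class = "slitflow_config_error")
  expect_error(synthetic_config(frame_size = c(-10, 100)),
               class = "slitflow_config_error")
  expect_error(synthetic_config(n_frames = 0),
               class = "slitflow_config_error")
  expect_error(synthetic_config(frame_size = c(64, 20)),
               class = "slitflow_config_error")   # no room for pre/post regions
  expect_error(generate_video(list()), class = "slitflow_config_error")
})

test_that("a cell-free video is pure background noise with empty truth", {
  g <- generate_video(tiny_config(n_cells = 0L, n_frames = 5L))
  expect_length(g$video$frames, 5L)
  expect_equal(nrow(g$truth$cells), 0L)
  expect_equal(nrow(g$truth$trajectory), 0L)
  # away from the barrier band the frame is just noise around the background
  patch <- g$video$frames[[1]][, 1:40]
  expect_lt(abs(mean(patch) - 0.85), 0.02)
  expect_lt(sd(patch), 0.05)
})

test_that("the same seed reproduces the frame stack bit for bit", {
  cfg <- tiny_config(seed = 9L, n_frames = 12L)
  g1 <- generate_video(cfg)
  g2 <- generate_video(cfg)
  expect_identical(g1$video$frames, g2$video$frames)
  expect_identical(g1$truth$trajectory, g2$truth$trajectory)
  # a different seed gives different pixels
  g3 <- generate_video(tiny_config(seed = 10L, n_frames = 12L))
  expect_false(identical(g1$video$frames, g3$video$frames))
})

test_that("abnormal cells are drawn binomially, fixed by the seed", {
  cfg <- synthetic_config(n_frames = 2L, n_cells = 100L,
                          frame_size = c(256L, 256L), condition = "healthy",
                          abnormal_fraction = 0.05, seed = 77L)
  g <- generate_video(cfg)
  n_ab <- sum(g$truth$cells$shape_class == "abnormal")
  expect_identical(n_ab, 5L)            # frozen draw for this seed
  expect_identical(sum(generate_video(cfg)$truth$cells$shape_class ==
                         "abnormal"), 5L)
  expect_equal(nrow(g$truth$cells), 100L)   # exactly one truth row per cell
})

test_that("cohort generation honours the requested per-condition counts", {
  base <- tiny_config(n_frames = 4L, n_cells = 2L)
  cohort <- generate_cohort(c(healthy = 30, SCD = 11, THAL = 10, HS = 28),
                            base, seed = 3L)
  expect_length(cohort, 79L)
  conds <- vapply(cohort, function(x) x$truth$condition, character(1))
  expect_equal(unname(table(conds)[c("healthy", "SCD", "THAL", "HS")]),
               c(30L, 11L, 10L, 28L), ignore_attr = TRUE)
  expect_identical(generate_cohort(c(healthy = 0), base, seed = 1L), list())
})

test_that("per-video seeds differ but the cohort is reproducible", {
  base <- tiny_config(n_frames = 6L, n_cells = 3L)
  c1 <- generate_cohort(c(healthy = 2), base, seed = 5L)
  c2 <- generate_cohort(c(healthy = 2), base, seed = 5L)
  expect_identical(c1[[1]]$video$frames, c2[[1]]$video$frames)
  expect_identical(c1[[2]]$video$frames, c2[[2]]$video$frames)
  expect_false(identical(c1[[1]]$video$frames, c1[[2]]$video$frames))
})

test_that("abnormal shape targets are separated from normal by a margin", {
  for (cond in c("SCD", "THAL", "HS")) {
    g <- generate_video(tiny_config(condition = cond, abnormal_fraction = 1,
                                    n_frames = 3L, n_cells = 6L))
    tgt <- g$truth$cells$ecc_target
    # every abnormal target differs from the normal resting value by >= 0.3
    expect_true(all(abs(tgt - 0.15) >= 0.3 | g$truth$cells$radius < 7))
    if (cond == "SCD") expect_true(all(tgt >= 0.8))
    if (cond == "HS") expect_true(all(g$truth$cells$radius < 7))
  }
})

test_that("rendered normal cells are measurably compact after the barrier", {
  cfg <- synthetic_config(n_frames = 80L, n_cells = 3L, condition = "healthy",
                          abnormal_fraction = 0, noise_sigma = 0.005,
                          defocus_prob = 0, seed = 21L)
  g <- generate_video(cfg)
  tr <- g$truth$trajectory
  sel <- tr[tr$col > cfg$barrier_x + 25 & tr$col < ncol(g$video$frames[[1]]) - 15 &
              !tr$overlapping, ]
  expect_gt(nrow(sel), 0)
  # independent moment oracle on a thresholded patch around the truth centre
  eccs <- vapply(seq_len(min(nrow(sel), 10L)), function(i) {
    fr <- g$video$frames[[sel$frame[i]]]
    rows <- round(sel$row[i]) + (-12:12)
    cols <- round(sel$col[i]) + (-12:12)
    patch <- fr[rows, cols]
    mask <- patch < 0.65
    cc <- which(mask, arr.ind = TRUE)
    x <- cc[, 2]; y <- cc[, 1]
    mu20 <- mean((x - mean(x))^2); mu02 <- mean((y - mean(y))^2)
    mu11 <- mean((x - mean(x)) * (y - mean(y)))
    common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    l1 <- (mu20 + mu02) / 2 + common; l2 <- (mu20 + mu02) / 2 - common
    sqrt(max(0, 1 - l2 / l1))
  }, numeric(1))
  expect_lt(mean(eccs), 0.4)
})

test_that("ground truth round-trips through its JSON writer", {
  g <- generate_video(tiny_config(n_frames = 5L, n_cells = 3L))
  path <- tempfile(fileext = ".json")
  write_truth(g$truth, path)
  back <- read_truth(path)
  expect_equal(back$condition, g$truth$condition)
  expect_equal(back$cells$radius, g$truth$cells$radius)
  expect_equal(back$trajectory$col, g$truth$trajectory$col)
})
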