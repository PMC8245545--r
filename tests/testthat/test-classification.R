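make_blobs <- function(centers, n_per, sd = 0.2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))
  }))
  list(x = x, y = rep(seq_len(nrow(centers)) - 1L, each = n_per))
}

test_that("widely separated two-class blobs are fit perfectly", {
  b <- make_blobs(rbind(c(-3, 0), c(3, 0)), 30)
  m <- train_classifier(b$x, b$y, "two_class")
  p <- predict(m, b$x)
  expect_equal(p$label, b$y)
  expect_true(all(abs(rowSums(as.matrix(p[, c("score_0", "score_1")])) - 1) < 1e-9))
})

test_that("four corner blobs are isolated by one-vs-all separators", {
  b <- make_blobs(rbind(c(-3, -3), c(3, -3), c(-3, 3), c(3, 3)), 25)
  m <- train_classifier(b$x, b$y, "four_class")
  p <- predict(m, b$x)
  expect_equal(p$label, b$y)
  sc <- as.matrix(p[, paste0("score_", 0:3)])
  expect_true(all(abs(rowSums(sc) - 1) < 1e-9))
  expect_equal(p$label, (0:3)[max.col(sc, ties.method = "first")])
})

test_that("a boundary point splits its scores evenly", {
  b <- make_blobs(rbind(c(-2, 0), c(2, 0)), 40, sd = 0.1)
  m <- train_classifier(b$x, b$y, "two_class")
  p <- predict(m, matrix(c(0, 0), 1, 2))
  expect_equal(unname(p$score_0), 0.5, tolerance = 0.01)
  expect_equal(unname(p$score_1), 0.5, tolerance = 0.01)
  # exactly tied scores resolve to the lower class index
  tied <- predict(m, rbind(colMeans(b$x)))
  expect_true(tied$label %in% 0:1)
})

test_that("a deep interior point concentrates its score", {
  b <- make_blobs(rbind(c(-3, -3), c(3, -3), c(-3, 3), c(3, 3)), 25)
  m <- train_classifier(b$x, b$y, "four_class")
  p <- predict(m, matrix(c(-6, 6), 1, 2))   # far inside class 2's corner
  expect_equal(p$label, 2L)
  expect_gt(p$score_2, 0.8)
})

test_that("softmax scoring is monotone in the decision values", {
  b <- make_blobs(rbind(c(-1, 0), c(1, 0)), 50, sd = 1.5, seed = 5)
  m <- train_classifier(b$x, b$y, "two_class")
  p <- predict(m, b$x)
  z <- sweep(sweep(b$x, 2, m$center, "-"), 2, m$scale, "/")
  dec <- drop(z %*% m$W[, 2] + m$b[2])
  expect_equal(order(p$score_1), order(dec))
})

test_that("degenerate training inputs raise errors", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(train_classifier(x, rep(0L, 10), "two_class"),
               class = "slitflow_training_error")
  expect_error(train_classifier(x, c(rep(0L, 5), rep(9L, 5)), "two_class"),
               class = "slitflow_training_error")
  m <- train_classifier(x, rep(c(0L, 1L), 5), "two_class")
  expect_error(predict(m, matrix(0, 2, 5)), class = "slitflow_shape_error")
})

test_that("LOEO folds never mix a video's ROIs into its own training set", {
  set.seed(3)
  n_vid <- 6L
  ids <- rep(sprintf("v%d", 1:n_vid), each = 10L)
  labs <- setNames(rep(c(0L, 1L), 3), sprintf("v%d", 1:n_vid))
  x <- matrix(rnorm(60 * 5), 60, 5) + labs[ids] * 3
  ft <- feature_table(x, data.frame(roi_id = sprintf("r%03d", 1:60),
                                    video_id = ids), "toy")
  res <- run_loeo(ft, ids, labs, "two_class",
                  selection = list(mode = "target_factor", value = 1))
  expect_equal(nrow(res$folds), n_vid)
  expect_equal(res$folds$n_train + res$folds$n_test, rep(60L, n_vid))
  expect_setequal(res$predictions$roi_id, ft$roi_index$roi_id)
  # each fold's predictions cover exactly the held-out video
  for (v in sprintf("v%d", 1:n_vid)) {
    expect_equal(sum(res$predictions$video_id == v), 10L)
  }
  # two videos: each fold trains on the other one only (here each video
  # carries a single class, so both folds are also skipped, with warnings)
  ft2 <- subset_feature_rows(ft, ids %in% c("v1", "v2"))
  suppressWarnings(
    r2 <- run_loeo(ft2, ids[ids %in% c("v1", "v2")], labs[1:2], "two_class",
                   selection = NULL))
  expect_equal(r2$folds$n_train, c(10L, 10L))
  expect_setequal(r2$skipped, c("v1", "v2"))
})

test_that("a single-class training fold is skipped with a warning", {
  ids <- rep(c("a", "b", "c"), each = 6L)
  labs <- c(a = 0L, b = 0L, c = 1L)
  set.seed(4)
  x <- matrix(rnorm(18 * 3), 18, 3)
  ft <- feature_table(x, data.frame(roi_id = sprintf("r%d", 1:18),
                                    video_id = ids), "toy")
  expect_warning(res <- run_loeo(ft, ids, labs, "two_class", selection = NULL),
                 "single-class")
  expect_equal(res$skipped, "c")
  expect_false("c" %in% res$predictions$video_id)
  expect_equal(res$folds$n_train_classes[res$folds$video_id == "c"], 1L)
})

test_that("perturbing the held-out video never changes that fold's mask", {
  set.seed(6)
  ids <- rep(sprintf("v%d", 1:4), each = 8L)
  labs <- setNames(c(0L, 1L, 0L, 1L), sprintf("v%d", 1:4))
  x <- matrix(rnorm(32 * 10), 32, 10)
  ft <- feature_table(x, data.frame(roi_id = sprintf("r%d", 1:32),
                                    video_id = ids), "toy")
  sel <- list(mode = "target_factor", value = 2)
  r1 <- run_loeo(ft, ids, labs, "two_class", selection = sel)
  x2 <- x
  x2[ids == "v2", ] <- x2[ids == "v2", ] * 100 + 7   # corrupt held-out rows
  ft2 <- feature_table(x2, ft$roi_index, "toy")
  r2 <- run_loeo(ft2, ids, labs, "two_class", selection = sel)
  expect_identical(r1$masks[["v2"]]$retained, r2$masks[["v2"]]$retained)
})

test_that("label-free features score no better than chance under LOEO", {
  # with uninformative features, grouped LOEO sits at or below chance (the
  # held-out video's label is the training minority), never above it
  set.seed(42)
  n_vid <- 20L
  ids <- rep(sprintf("v%02d", 1:n_vid), each = 8L)
  x <- matrix(rnorm(160 * 4), 160, 4)      # featureless noise
  labs <- setNames(sample(rep(c(0L, 1L), n_vid / 2)), sprintf("v%02d", 1:n_vid))
  ft <- feature_table(x, data.frame(roi_id = sprintf("r%d", 1:160),
                                    video_id = ids), "toy")
  res <- run_loeo(ft, ids, labs, "two_class", selection = NULL)
  acc <- mean(res$predictions$label == labs[res$predictions$video_id])
  expect_lt(acc, 0.65)
})

test_that("condition labels map onto the published class codes", {
  conds <- c("healthy", "SCD", "THAL", "HS")
  expect_equal(condition_to_label(conds, "two_class"), c(0L, 1L, 1L, 1L))
  expect_equal(condition_to_label(conds, "four_class"), 0:3)
})
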