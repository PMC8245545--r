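pred_from <- function(labels, scores = NULL, classes = 0:1, video_id = "v") {
  k <- length(classes)
  if (is.null(scores)) {
    scores <- matrix(1 / k, length(labels), k)
    for (i in seq_along(labels)) {
      scores[i, ] <- ifelse(classes == labels[i], 0.7, 0.3 / (k - 1))
    }
  }
  out <- data.frame(roi_id = sprintf("%s_%d", video_id, seq_along(labels)),
                    video_id = video_id, label = labels,
                    stringsAsFactors = FALSE)
  sc <- as.data.frame(scores)
  names(sc) <- paste0("score_", classes)
  out <- cbind(out, sc)
  attr(out, "class_labels") <- classes
  class(out) <- c("scored_predictions", "data.frame")
  out
}

test_that("majority voting picks the modal label with full evidence", {
  d <- majority_vote(pred_from(c(1L, 1L, 0L)))
  expect_equal(d$decided_class, 1L)
  expect_equal(unname(d$evidence), c(1L, 2L))
  expect_equal(sum(d$evidence), 3L)
})

test_that("majority ties break by total score, then lower class index", {
  p <- pred_from(c(0L, 1L), scores = rbind(c(0.4, 0.6), c(0.4, 0.6)))
  expect_equal(majority_vote(p)$decided_class, 1L)   # score sum 1.2 vs 0.8
  p2 <- pred_from(c(0L, 1L), scores = rbind(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(majority_vote(p2)$decided_class, 0L)  # full tie -> lower index
  empty <- pred_from(c(0L, 1L))[0, ]
  attr(empty, "class_labels") <- 0:1
  expect_error(majority_vote(empty), class = "slitflow_decision_error")
})

test_that("percentage limit uses strict exceedance", {
  p31 <- pred_from(c(rep(1L, 31), rep(0L, 69)))
  expect_equal(percentage_limit(p31, 0.30)$decided_class, 1L)
  p30 <- pred_from(c(rep(1L, 30), rep(0L, 70)))
  expect_equal(percentage_limit(p30, 0.30)$decided_class, 0L)
  none <- pred_from(rep(0L, 25))
  expect_equal(percentage_limit(none, 0.30)$decided_class, 0L)
  expect_equal(percentage_limit(none, 0.01)$decided_class, 0L)
})

test_that("percentage limit rejects four-class input and bad limits", {
  p4 <- pred_from(c(0L, 2L, 3L), classes = 0:3)
  expect_error(percentage_limit(p4, 0.3), class = "slitflow_usage_error")
  p <- pred_from(c(0L, 1L))
  expect_error(percentage_limit(p, 0), class = "slitflow_usage_error")
  expect_error(percentage_limit(p, 1), class = "slitflow_usage_error")
})

test_that("maximum trustiness sums scores and normalises the winner", {
  p <- pred_from(0L, scores = matrix(c(0.7, 0.1, 0.1, 0.1), 1), classes = 0:3)
  d <- max_trustiness(p)
  expect_equal(d$decided_class, 0L)
  expect_equal(d$normalized_score, 0.7)

  p2 <- pred_from(c(0L, 1L), scores = rbind(c(0.6, 0.4, 0, 0),
                                            c(0.3, 0.7, 0, 0)), classes = 0:3)
  d2 <- max_trustiness(p2)
  expect_equal(d2$decided_class, 1L)                  # sums (0.9, 1.1, 0, 0)
  expect_equal(unname(d2$evidence), c(0.9, 1.1, 0, 0))

  pu <- pred_from(rep(0L, 4), scores = matrix(0.25, 4, 4), classes = 0:3)
  du <- max_trustiness(pu)
  expect_equal(du$decided_class, 0L)                  # tie -> lowest index
  expect_equal(du$normalized_score, 0.25)
})

test_that("trustiness is invariant to ROI ordering", {
  set.seed(5)
  p <- random_predictions(40, 0:3)
  d1 <- max_trustiness(p)
  perm <- p[sample(40), ]
  attr(perm, "class_labels") <- 0:3
  d2 <- max_trustiness(perm)
  expect_equal(d1$decided_class, d2$decided_class)
  expect_equal(d1$normalized_score, d2$normalized_score)
})

test_that("majority and the 50% limit agree away from exact ties", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    p <- random_predictions(n, 0:1, video_id = sprintf("v%d", i))
    frac1 <- mean(p$label == 1L)
    if (frac1 == 0.5) next
    expect_equal(majority_vote(p)$decided_class,
                 percentage_limit(p, 0.5)$decided_class)
  }
})

test_that("confusion matrices recount the decision list exactly", {
  set.seed(9)
  n_vid <- 30L
  preds <- do.call(rbind, lapply(seq_len(n_vid), function(i)
    random_predictions(sample(5:20, 1), 0:1, sprintf("v%02d", i))))
  attr(preds, "class_labels") <- 0:1
  class(preds) <- c("scored_predictions", "data.frame")
  dec <- decide_videos(preds, "majority")
  truth <- setNames(sample(0:1, n_vid, TRUE), sprintf("v%02d", seq_len(n_vid)))
  cm <- build_confusion(dec, truth, 0:1)
  expect_equal(sum(cm), n_vid)
  for (t in 0:1) for (d in 0:1) {
    expect_equal(cm[t + 1, d + 1],
                 sum(truth[dec$video_id] == t & dec$decided == d))
  }
  expect_error(build_confusion(dec, truth[-1], 0:1),
               class = "slitflow_decision_error")
})

test_that("efficiency is the trace over the total", {
  expect_equal(efficiency(diag(c(5, 7))), 1)
  expect_equal(efficiency(matrix(c(3, 1, 1, 3), 2)), 0.75)
  expect_error(efficiency(matrix(0, 2, 2)), class = "slitflow_decision_error")
  expect_equal(format_efficiency(0.911392), "91%")
})

test_that("score profiles pair each video with its winning score and truth", {
  p1 <- random_predictions(10, 0:3, "va")
  p2 <- random_predictions(12, 0:3, "vb")
  preds <- rbind(p1, p2)
  attr(preds, "class_labels") <- 0:3
  class(preds) <- c("scored_predictions", "data.frame")
  dec <- decide_videos(preds, "max_trustiness")
  prof <- score_profile(dec, c(va = 0L, vb = 2L))
  expect_equal(prof$video_id, c("va", "vb"))
  expect_equal(prof$truth, c(0L, 2L))
  expect_true(all(prof$normalized_score > 0 & prof$normalized_score <= 1))
})
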