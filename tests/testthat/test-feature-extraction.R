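test_that("descriptors are deterministic and correctly shaped", {
  img <- render_ellipse_frame(32, 16, 16, 8, 8)
  f1 <- handcrafted_descriptors(img)
  f2 <- handcrafted_descriptors(img)
  expect_identical(f1, f2)
  expect_named(f1, handcrafted_feature_names())
  expect_false(anyNA(f1))
})

test_that("a disk reads as circular, an ellipse as eccentric", {
  disk <- handcrafted_descriptors(render_ellipse_frame(48, 24, 24, 10, 10))
  expect_lt(disk["eccentricity"], 0.2)
  expect_gt(disk["circularity"], 0.8)
  expect_gt(disk["solidity"], 0.85)

  # 3:1 axis ratio: closed-form eccentricity sqrt(1 - (b/a)^2) = 0.9428
  ell <- handcrafted_descriptors(render_ellipse_frame(48, 24, 24, 15, 5))
  expect_equal(unname(ell["eccentricity"]), sqrt(1 - (1 / 3)^2),
               tolerance = 0.02)
})

test_that("a disk is more circular than a same-area ellipse", {
  disk <- handcrafted_descriptors(render_ellipse_frame(64, 32, 32, 9, 9))
  ell <- handcrafted_descriptors(render_ellipse_frame(64, 32, 32, 27, 3))
  expect_lt(abs(disk["area"] - ell["area"]) / disk["area"], 0.15)
  expect_gt(disk["circularity"], ell["circularity"])
})

test_that("a blank crop yields a zero shape block and background stats", {
  set.seed(12)
  img <- matrix(0.85 + rnorm(32 * 32, 0, 0.02), 32, 32)
  f <- handcrafted_descriptors(img)
  shape_block <- c("area", "perimeter", "circularity", "eccentricity",
                   "solidity", paste0("hu", 1:7))
  expect_true(all(f[shape_block] == 0))
  expect_equal(unname(f["fg_mean"]), mean(img), tolerance = 1e-8)
})

test_that("Hu moments are invariant to 90-degree rotation", {
  img <- render_ellipse_frame(48, 22, 26, 14, 6, theta = pi / 6)
  rot <- t(img)[ncol(img):1, ]                  # exact 90-degree rotation
  f <- handcrafted_descriptors(img)
  fr <- handcrafted_descriptors(rot)
  expect_equal(unname(f[paste0("hu", 1:7)]), unname(fr[paste0("hu", 1:7)]),
               tolerance = 1e-6)
})

test_that("the pool5 dimensionality follows from the layer arithmetic", {
  # propagate 224 -> 55 -> 27 -> 27 -> 13 -> 13 -> 13 -> 13 -> 6 by hand
  n <- 224
  n <- (n + 4 - 11) %/% 4 + 1; n <- (n - 3) %/% 2 + 1
  n <- (n + 4 - 5) %/% 1 + 1;  n <- (n - 3) %/% 2 + 1
  n <- (n + 2 - 3) %/% 1 + 1;  n <- (n + 2 - 3) %/% 1 + 1
  n <- (n + 2 - 3) %/% 1 + 1;  n <- (n - 3) %/% 2 + 1
  expect_identical(alexnet_feature_dim(224L), as.integer(256 * n * n))
  expect_identical(alexnet_feature_dim(224L), 9216L)
})

test_that("the CNN backend codes ROIs into deterministic pool5 vectors", {
  g <- generate_video(tiny_config(n_frames = 5L, n_cells = 3L))
  det <- detect_video(g$video, 4, 12)
  rois <- extract_rois(g$video, det, 32L, g$video$barrier_x)
  rois <- subset_rois(rois, seq_len(min(2L, nrow(rois$info))))
  wfile <- synthetic_cnn_weights(seed = 3L)
  be <- feature_backend("cnn", weights_file = wfile)
  ft <- extract_features(rois, be)
  expect_equal(ncol(ft$matrix), alexnet_feature_dim(224L))
  expect_equal(nrow(ft$matrix), nrow(rois$info))
  expect_equal(ft$backend_name, "cnn")
  ft2 <- extract_features(rois, be)
  expect_identical(ft$matrix, ft2$matrix)
  # backend swap changes the width, never the row alignment
  fh <- extract_features(rois, "handcrafted")
  expect_identical(fh$roi_index$roi_id, ft$roi_index$roi_id)
  expect_false(ncol(fh$matrix) == ncol(ft$matrix))
  unlink(wfile)
})

test_that("a missing weights file raises a capability error naming the fallback", {
  g <- generate_video(tiny_config(n_frames = 3L, n_cells = 2L))
  det <- detect_video(g$video, 4, 12)
  rois <- extract_rois(g$video, det, 32L, g$video$barrier_x)
  err <- expect_error(
    extract_features(rois, feature_backend("cnn")),
    class = "slitflow_capability_error")
  expect_match(conditionMessage(err), "handcrafted")
})
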