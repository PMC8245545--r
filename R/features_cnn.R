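# Pretrained-CNN feature coding: an AlexNet-geometry convolutional feature
# extractor evaluated up to its third max-pooling layer (pool5). Weights are
# read from a local RDS file; the package never downloads anything and never
# trains or fine-tunes the network.

#' AlexNet feature-extractor layer geometry
#'
#' Convolution/pooling stack of the standard AlexNet feature extractor
#' (five convolutions, three max-poolings); the third max-pooling output is
#' the pool5 coding layer.
#'
#' @return A list of layer descriptors (`type`, kernel `k`, stride `s`,
#'   padding `p`, output channels `out` for convolutions).
#' @export
alexnet_layers <- function() {
  list(
    list(type = "conv", name = "conv1", k = 11L, s = 4L, p = 2L, out = 64L),
    list(type = "pool", k = 3L, s = 2L),
    list(type = "conv", name = "conv2", k = 5L, s = 1L, p = 2L, out = 192L),
    list(type = "pool", k = 3L, s = 2L),
    list(type = "conv", name = "conv3", k = 3L, s = 1L, p = 1L, out = 384L),
    list(type = "conv", name = "conv4", k = 3L, s = 1L, p = 1L, out = 256L),
    list(type = "conv", name = "conv5", k = 3L, s = 1L, p = 1L, out = 256L),
    list(type = "pool", k = 3L, s = 2L))
}

#' Flattened pool5 dimensionality from the architecture definition
#'
#' Propagates the spatial size through every layer
#' (`n' = floor((n + 2p - k) / s) + 1`) and multiplies the final channel
#' count by the final spatial area. For the standard 224-px input this is
#' 256 x 6 x 6 = 9216.
#'
#' @param input_size network input side in pixels.
#' @return Integer feature-vector length.
#' @export
alexnet_feature_dim <- function(input_size = 224L) {
  n <- as.integer(input_size)
  ch <- 3L
  for (ly in alexnet_layers()) {
    p <- if (is.null(ly$p)) 0L else ly$p
    n <- (n + 2L * p - ly$k) %/% ly$s + 1L
    if (ly$type == "conv") ch <- ly$out
  }
  ch * n * n
}

# Zero-pad an [H, W, C] array spatially.
pad_array <- function(a, p) {
  if (p == 0L) return(a)
  d <- dim(a)
  out <- array(0, dim = c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- a
  out
}

# 2-D convolution via im2col + matrix multiply.
# a: [H, W, C]; w: [k, k, C, O]; b: length O.
conv2d <- function(a, w, b, s, p) {
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  if (dim(a)[3] != cin) {
    abort("weight/input channel mismatch in conv layer", "slitflow_shape_error")
  }
  a <- pad_array(a, p)
  hp <- dim(a)[1]; wp <- dim(a)[2]
  oh <- (hp - k) %/% s + 1L
  ow <- (wp - k) %/% s + 1L
  # linear indices of each patch's top-left corner within one channel slice
  tl <- as.vector(outer((0:(oh - 1L)) * s + 1L, (0:(ow - 1L)) * s * hp, "+"))
  off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * hp, "+"))
  gather <- outer(tl, off, "+")                 # (oh*ow) x (k*k)
  patches <- matrix(0, oh * ow, k * k * cin)
  slice_len <- hp * wp
  for (c in seq_len(cin)) {
    sl <- a[, , c]
    patches[, ((c - 1L) * k * k + 1L):(c * k * k)] <- sl[gather]
  }
  wm <- matrix(w, nrow = k * k * cin, ncol = cout)
  out <- patches %*% wm
  out <- sweep(out, 2L, b, "+")
  array(out, dim = c(oh, ow, cout))
}

maxpool2d <- function(a, k, s) {
  h <- dim(a)[1]; w <- dim(a)[2]
  oh <- (h - k) %/% s + 1L
  ow <- (w - k) %/% s + 1L
  out <- array(-Inf, dim = c(oh, ow, dim(a)[3]))
  ri <- seq(1L, by = s, length.out = oh)
  ci <- seq(1L, by = s, length.out = ow)
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    out <- pmax(out, a[ri + di, ci + dj, , drop = FALSE])
  }
  out
}

load_cnn_weights <- function(weights_file) {
  if (is.null(weights_file) || !is.character(weights_file) ||
      !file.exists(weights_file)) {
    abort(paste("CNN backend unavailable: no local weights file was found and",
                "nothing is downloaded. Use feature_backend(\"handcrafted\")",
                "or point weights_file at a local RDS weights file."),
          "slitflow_capability_error")
  }
  w <- readRDS(weights_file)
  convs <- Filter(function(l) l$type == "conv", alexnet_layers())
  for (ly in convs) {
    if (is.null(w[[ly$name]]) || is.null(w[[ly$name]]$W)) {
      abort(sprintf("weights file is missing layer '%s'", ly$name),
            "slitflow_capability_error")
    }
  }
  w
}

# Grayscale ROI -> [input, input, 3] array: bilinear resize + channel
# replication (fixed preprocessing defaults, documented in the vignette).
cnn_preprocess <- function(img, input_size) {
  r <- EBImage::imageData(EBImage::resize(EBImage::Image(img),
                                          w = input_size, h = input_size))
  array(rep(r, 3L), dim = c(dim(r), 3L))
}

cnn_pool5_features <- function(img, weights, input_size = 224L) {
  a <- cnn_preprocess(img, input_size)
  for (ly in alexnet_layers()) {
    if (ly$type == "conv") {
      lw <- weights[[ly$name]]
      a <- conv2d(a, lw$W, lw$b, ly$s, ly$p)
      a <- pmax(a, 0)                            # ReLU
    } else {
      a <- maxpool2d(a, ly$k, ly$s)
    }
  }
  as.numeric(a)
}

#' Write synthetic (random) CNN weights for offline testing
#'
#' Pretrained ImageNet weights cannot be redistributed with the package and
#' are never downloaded; this helper writes a *synthetic* random-weight file
#' in the expected RDS format so the CNN code path (resize, channel
#' replication, conv/pool forward pass, pool5 flattening) can be exercised
#' end-to-end offline. Features from synthetic weights are deterministic but
#' carry no pretrained semantics.
#'
#' @param path output RDS path.
#' @param seed integer seed for the weight draw.
#' @param sd standard deviation of the Gaussian weight initialisation.
#' @return `path`, invisibly.
#' @export
synthetic_cnn_weights <- function(path = tempfile(fileext = ".rds"),
                                  seed = 1L, sd = 0.05) {
  layers <- alexnet_layers()
  cin <- 3L
  w <- list()
  with_seed(seed, {
    for (ly in layers) {
      if (ly$type != "conv") next
      w[[ly$name]] <- list(
        W = array(rnorm(ly$k * ly$k * cin * ly$out, 0, sd),
                  dim = c(ly$k, ly$k, cin, ly$out)),
        b = rep(0, ly$out))
      cin <- ly$out
    }
  })
  saveRDS(w, path)
  invisible(path)
}
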