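# internal helpers shared across modules

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' @noRd
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "slitflow_error", "error", "condition")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Row-wise softmax, numerically stable.
softmax_rows <- function(d) {
  d <- as.matrix(d)
  m <- apply(d, 1L, max)
  e <- exp(d - m)
  e / rowSums(e)
}

# Replicate-pad a matrix by one pixel on every side.
pad_replicate1 <- function(m) {
  m[c(1L, seq_len(nrow(m)), nrow(m)), c(1L, seq_len(ncol(m)), ncol(m))]
}

# 3x3 box mean with replicated borders (used for mild defocus emulation).
box_blur3 <- function(m) {
  p <- pad_replicate1(m)
  h <- nrow(m); w <- ncol(m)
  sh <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  (sh(-1L, -1L) + sh(-1L, 0L) + sh(-1L, 1L) +
     sh(0L, -1L) + sh(0L, 0L) + sh(0L, 1L) +
     sh(1L, -1L) + sh(1L, 0L) + sh(1L, 1L)) / 9
}

# 3x3 box *sum* (no normalisation), replicated borders.
box_sum3 <- function(m) box_blur3(m) * 9

# Per-column sample variance (denominator n - 1).
col_variances <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
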