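# Rendering constants shared by the generator and its consumers.
.bg_level <- 0.85            # bright background gray level
.band_half_width <- 3L       # slit-barrier band half-width, px
.rest_eccentricity <- 0.15   # relaxed projected eccentricity of a normal RBC
.slit_eccentricity <- 0.85   # every cell elongates inside the slit band

rhha_conditions <- function() c("healthy", "SCD", "THAL", "HS")

#' Configuration for the synthetic slit-barrier video generator
#'
#' Parameterises one synthetic time-lapse recording of red blood cells being
#' pushed left-to-right across a vertical slit-barrier band. The defaults
#' mirror the acquisition conditions of the microfluidic platform the package
#' models: roughly 1000 frames per video at 85 frames/s, cells of ~8 px
#' projected radius, and per-video mixtures in which only a fraction of a
#' patient's cells behave abnormally.
#'
#' @param frame_size integer (height, width) of each frame in pixels.
#' @param n_frames number of frames to render.
#' @param fps nominal acquisition rate, frames per second (metadata only).
#' @param barrier_x column index (1-based) of the slit-barrier band centre;
#'   defaults to the middle column.
#' @param cell_radius_px named vector `c(mean =, sd =)` of the projected cell
#'   radius in pixels.
#' @param n_cells number of cells crossing the field of view.
#' @param velocity_px_per_frame named vector `c(mean =, sd =)` of per-cell
#'   horizontal velocity.
#' @param condition video-level class: `"healthy"`, `"SCD"`, `"THAL"` or
#'   `"HS"`.
#' @param abnormal_fraction proportion in `[0, 1]` of cells drawn from the
#'   condition's abnormal shape model. Defaults to 0.05 for healthy videos
#'   (old cells exist even in controls) and 0.8 for disease videos (not every
#'   cell of a patient is abnormal).
#' @param noise_sigma standard deviation of additive Gaussian gray-level
#'   noise.
#' @param defocus_prob per-frame probability of a mild defocus (box blur).
#' @param seed integer seed fixing the video byte-for-byte.
#' @param video_id optional identifier; defaults to a condition/seed tag.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(frame_size = c(96L, 256L),
                             n_frames = 1000L,
                             fps = 85,
                             barrier_x = NULL,
                             cell_radius_px = c(mean = 8, sd = 0.8),
                             n_cells = 12L,
                             velocity_px_per_frame = c(mean = 2, sd = 0.4),
                             condition = c("healthy", "SCD", "THAL", "HS"),
                             abnormal_fraction = NULL,
                             noise_sigma = 0.02,
                             defocus_prob = 0.02,
                             seed = 1L,
                             video_id = NULL) {
  condition <- match.arg(condition)
  abnormal_fraction_user <- !is.null(abnormal_fraction)
  if (!abnormal_fraction_user) {
    abnormal_fraction <- if (condition == "healthy") 0.05 else 0.8
  }
  if (length(frame_size) != 2L || any(!is.finite(frame_size)) ||
      any(frame_size < 8) || any(frame_size != round(frame_size))) {
    abort("frame_size must be two positive integers (height, width) >= 8",
          "slitflow_config_error")
  }
  frame_size <- as.integer(frame_size)
  if (!is_count(n_frames) || n_frames < 1) {
    abort("n_frames must be a positive integer", "slitflow_config_error")
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    abort("fps must be a positive number", "slitflow_config_error")
  }
  if (is.null(barrier_x)) barrier_x <- as.integer(round(frame_size[2L] / 2))
  if (!is_count(barrier_x) || barrier_x < 1 || barrier_x > frame_size[2L]) {
    abort("barrier_x must be a column index inside the frame",
          "slitflow_config_error")
  }
  rmean <- unname(cell_radius_px["mean"]); rsd <- unname(cell_radius_px["sd"])
  if (is.na(rmean) || rmean <= 0 || is.na(rsd) || rsd < 0) {
    abort("cell_radius_px must provide a positive mean and non-negative sd",
          "slitflow_config_error")
  }
  if (!is_count(n_cells)) {
    abort("n_cells must be a non-negative integer", "slitflow_config_error")
  }
  vmean <- unname(velocity_px_per_frame["mean"])
  vsd <- unname(velocity_px_per_frame["sd"])
  if (is.na(vmean) || vmean <= 0 || is.na(vsd) || vsd < 0) {
    abort("velocity_px_per_frame must provide a positive mean", "slitflow_config_error")
  }
  if (!is.numeric(abnormal_fraction) || length(abnormal_fraction) != 1L ||
      is.na(abnormal_fraction) || abnormal_fraction < 0 || abnormal_fraction > 1) {
    abort("abnormal_fraction must lie in [0, 1]", "slitflow_config_error")
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    abort("noise_sigma must be non-negative", "slitflow_config_error")
  }
  if (!is.numeric(defocus_prob) || defocus_prob < 0 || defocus_prob > 1) {
    abort("defocus_prob must lie in [0, 1]", "slitflow_config_error")
  }
  if (!is_count(abs(seed))) {
    abort("seed must be an integer", "slitflow_config_error")
  }
  # the frame must hold the band plus usable pre/post regions
  if (barrier_x - .band_half_width - 2 * rmean < 1 ||
      barrier_x + .band_half_width + 2 * rmean > frame_size[2L]) {
    abort("frame too narrow to contain the barrier band plus pre/post regions",
          "slitflow_config_error")
  }
  if (is.null(video_id)) video_id <- sprintf("%s_s%d", condition, as.integer(seed))
  structure(
    list(frame_size = frame_size, n_frames = as.integer(n_frames), fps = fps,
         barrier_x = as.integer(barrier_x),
         cell_radius_px = c(mean = rmean, sd = rsd),
         n_cells = as.integer(n_cells),
         velocity_px_per_frame = c(mean = vmean, sd = vsd),
         condition = condition,
         abnormal_fraction = abnormal_fraction,
         abnormal_fraction_user = abnormal_fraction_user,
         noise_sigma = noise_sigma, defocus_prob = defocus_prob,
         seed = as.integer(seed), video_id = video_id),
    class = "synthetic_config")
}

# Post-barrier shape model per condition. Normal cells relax back to a
# near-circular projection within ~4 px of the band; abnormal cells keep a
# class-specific projection (relaxation length effectively infinite).
shape_model <- function(condition, abnormal) {
  if (!abnormal) {
    return(list(ecc_target = .rest_eccentricity, relax_len = 4, depth = 0.40,
                radius_scale = 1, inclusion = FALSE, irregularity = 0))
  }
  switch(condition,
    healthy = list(ecc_target = 0.45, relax_len = Inf, depth = 0.40,
                   radius_scale = 1, inclusion = FALSE, irregularity = 0),
    SCD = list(ecc_target = 0.80, relax_len = Inf, depth = 0.40,
               radius_scale = 1.05, inclusion = FALSE, irregularity = 0),
    THAL = list(ecc_target = 0.50, relax_len = Inf, depth = 0.40,
                radius_scale = 1, inclusion = TRUE, irregularity = 0.05),
    HS = list(ecc_target = 0.10, relax_len = Inf, depth = 0.55,
              radius_scale = 0.65, inclusion = FALSE, irregularity = 0))
}

# Projected eccentricity of one cell as a function of its centre column.
# All cells elongate inside the band; recovery past the band is an
# exponential relaxation with class-specific target and length.
eccentricity_profile <- function(x, radius, barrier_x, ecc_target, relax_len) {
  pre_edge <- barrier_x - .band_half_width - radius
  post_edge <- barrier_x + .band_half_width
  e <- rep(.rest_eccentricity, length(x))
  inside <- x >= pre_edge & x <= post_edge
  e[inside] <- .slit_eccentricity
  after <- x > post_edge
  if (any(after)) {
    d <- x[after] - post_edge
    decay <- if (is.finite(relax_len)) exp(-d / relax_len) else rep(1, length(d))
    e[after] <- ecc_target + (.slit_eccentricity - ecc_target) * decay
  }
  e
}

# Semi-axes of an area-preserving ellipse with radius r and eccentricity e
# (major axis along the flow direction).
ellipse_axes <- function(r, e) {
  q <- (1 - e^2)^0.25
  list(a = r / q, b = r * q)
}

# Static background: bright field plus the dark slit-barrier band with
# low-contrast slit openings (period 12 rows, 4 rows open).
render_background <- function(h, w, barrier_x) {
  base <- matrix(.bg_level, h, w)
  cols <- max(1L, barrier_x - .band_half_width):min(w, barrier_x + .band_half_width)
  band <- ifelse((seq_len(h) %% 12L) < 4L, 0.48, 0.35)
  base[, cols] <- matrix(band, h, length(cols))
  base
}

# Subtract one anti-aliased (possibly irregular) ellipse from a frame.
render_cell <- function(frame, cy, cx, a, b, depth, irregularity = 0,
                        irr_phase = 0, inclusion = FALSE, incl_phase = 0) {
  h <- nrow(frame); w <- ncol(frame)
  r0 <- max(1L, floor(cy - b - 3)); r1 <- min(h, ceiling(cy + b + 3))
  c0 <- max(1L, floor(cx - a - 3)); c1 <- min(w, ceiling(cx + a + 3))
  if (r0 > r1 || c0 > c1) return(frame)
  ys <- (r0:r1) - cy
  xs <- (c0:c1) - cx
  d <- sqrt(outer((ys / b)^2, (xs / a)^2, "+"))
  if (irregularity > 0) {
    th <- outer(ys, xs, function(y, x) atan2(y, x))
    d <- d * (1 + irregularity * sin(3 * th + irr_phase))
  }
  alpha <- clamp01((1 - d) * b + 0.5)
  patch <- frame[r0:r1, c0:c1] - depth * alpha
  if (inclusion) {
    ri <- 0.30 * min(a, b)
    icy <- cy + 0.35 * b * sin(incl_phase)
    icx <- cx + 0.35 * a * cos(incl_phase)
    dd <- sqrt(outer(((r0:r1) - icy)^2, ((c0:c1) - icx)^2, "+"))
    patch <- patch - 0.30 * clamp01(ri - dd + 0.5)
  }
  frame[r0:r1, c0:c1] <- patch
  frame
}

#' Generate one synthetic slit-barrier video with ground truth
#'
#' Renders `config$n_frames` grayscale frames in which quasi-circular cells
#' move left-to-right across a dark vertical slit-barrier band. Every cell is
#' rendered elongated while inside the band; normal cells relax back to a
#' near-circular projection shortly after it, abnormal cells keep a
#' class-specific projection (elongated for SCD, small/round/high-contrast
#' for HS, irregular with an internal dark inclusion for THAL). The output is
#' deterministic given `config$seed` and frames are quantised to 8-bit levels
#' so lossless writers round-trip them exactly.
#'
#' @param config a [synthetic_config()].
#' @return A list with components `video` (a [video_record()]) and `truth`
#'   (class `ground_truth`: `$cells` — one row per rendered cell with its
#'   shape class and morphology parameters; `$trajectory` — per-frame centres,
#'   projected eccentricity, in-frame and overlap flags).
#' @export
generate_video <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("config must be a synthetic_config", "slitflow_config_error")
  }
  h <- config$frame_size[1L]; w <- config$frame_size[2L]
  n <- config$n_cells; nf <- config$n_frames
  bx <- config$barrier_x
  with_seed(config$seed, {
    if (n > 0L) {
      radius <- pmin(pmax(rnorm(n, config$cell_radius_px["mean"],
                                config$cell_radius_px["sd"]), 4), 14)
      abnormal <- runif(n) < config$abnormal_fraction
      models <- lapply(abnormal, function(a) shape_model(config$condition, a))
      radius <- radius * vapply(models, `[[`, numeric(1), "radius_scale")
      rows <- runif(n, 10, h - 10)
      vel <- pmax(abs(rnorm(n, config$velocity_px_per_frame["mean"],
                            config$velocity_px_per_frame["sd"])), 0.5)
      t_cross <- runif(n, 0.15, 0.85) * nf
      start_col <- bx - vel * t_cross
      irr_phase <- runif(n, 0, 2 * pi)
      incl_phase <- runif(n, 0, 2 * pi)
      cells <- data.frame(
        cell_id = seq_len(n),
        shape_class = ifelse(abnormal, "abnormal", "normal"),
        radius = radius,
        ecc_target = vapply(models, `[[`, numeric(1), "ecc_target"),
        relax_len = vapply(models, `[[`, numeric(1), "relax_len"),
        depth = vapply(models, `[[`, numeric(1), "depth"),
        row = rows, start_col = start_col, velocity = vel,
        inclusion = vapply(models, `[[`, logical(1), "inclusion"),
        irregularity = vapply(models, `[[`, numeric(1), "irregularity"),
        stringsAsFactors = FALSE)
    } else {
      cells <- data.frame(cell_id = integer(), shape_class = character(),
                          radius = numeric(), ecc_target = numeric(),
                          relax_len = numeric(), depth = numeric(),
                          row = numeric(), start_col = numeric(),
                          velocity = numeric(), inclusion = logical(),
                          irregularity = numeric(), stringsAsFactors = FALSE)
    }

    # per-frame per-cell centre columns and eccentricities
    if (n > 0L) {
      cols_mat <- outer(cells$start_col, rep(1, nf)) +
        outer(cells$velocity, seq_len(nf) - 1)
      ecc_mat <- t(vapply(seq_len(n), function(i) {
        eccentricity_profile(cols_mat[i, ], cells$radius[i], bx,
                             cells$ecc_target[i], cells$relax_len[i])
      }, numeric(nf)))
      if (nf == 1L) ecc_mat <- matrix(ecc_mat, nrow = n)
    }

    background <- render_background(h, w, bx)
    frames <- vector("list", nf)
    traj <- vector("list", nf)
    for (f in seq_len(nf)) {
      frame <- background
      if (n > 0L) {
        xs <- cols_mat[, f]
        visible <- which(xs > -2 * cells$radius - 4 & xs < w + 2 * cells$radius + 4)
        for (i in visible) {
          ax <- ellipse_axes(cells$radius[i], ecc_mat[i, f])
          frame <- render_cell(frame, cells$row[i], xs[i], ax$a, ax$b,
                               cells$depth[i], cells$irregularity[i],
                               irr_phase[i], cells$inclusion[i], incl_phase[i])
        }
        # overlap marking: centre distance below the sum of radii
        overlapping <- rep(FALSE, n)
        if (length(visible) > 1L) {
          for (ii in seq_along(visible)[-1L]) {
            for (jj in seq_len(ii - 1L)) {
              i <- visible[ii]; j <- visible[jj]
              dx <- xs[i] - xs[j]; dy <- cells$row[i] - cells$row[j]
              if (dx * dx + dy * dy < (cells$radius[i] + cells$radius[j])^2) {
                overlapping[i] <- TRUE; overlapping[j] <- TRUE
              }
            }
          }
        }
        traj[[f]] <- data.frame(
          frame = f, cell_id = cells$cell_id, row = cells$row, col = xs,
          ecc = ecc_mat[, f],
          in_frame = xs >= 1 & xs <= w,
          overlapping = overlapping)
      }
      if (runif(1) < config$defocus_prob) frame <- box_blur3(frame)
      if (config$noise_sigma > 0) {
        frame <- frame + matrix(rnorm(h * w, 0, config$noise_sigma), h, w)
      }
      frames[[f]] <- round(clamp01(frame) * 255) / 255
    }
    trajectory <- if (n > 0L) do.call(rbind, traj) else
      data.frame(frame = integer(), cell_id = integer(), row = numeric(),
                 col = numeric(), ecc = numeric(), in_frame = logical(),
                 overlapping = logical())

    video <- video_record(frames, video_id = config$video_id, fps = config$fps,
                          condition = config$condition, barrier_x = bx)
    truth <- structure(
      list(cells = cells, trajectory = trajectory,
           condition = config$condition, barrier_x = bx, config = config),
      class = "ground_truth")
    list(video = video, truth = truth)
  })
}

#' Generate a cohort of synthetic videos
#'
#' Produces the requested number of videos per condition with per-video seeds
#' derived deterministically from one cohort seed, so the whole cohort is
#' reproducible from a single integer.
#'
#' @param counts named vector of video counts, names among
#'   `c("healthy", "SCD", "THAL", "HS")`, e.g. the study-sized split
#'   `c(healthy = 30, SCD = 11, THAL = 10, HS = 28)`.
#' @param base_config a [synthetic_config()] providing all non-condition
#'   parameters. Unless the base config was built with an explicit
#'   `abnormal_fraction`, each condition uses its own default fraction.
#' @param seed cohort-level integer seed.
#' @param abnormal_fraction optional override of the per-condition abnormal
#'   cell fraction: a single number for all conditions or a named vector
#'   (e.g. `c(healthy = 0, SCD = 1, THAL = 1, HS = 1)` for a strongly
#'   separated cohort of unambiguous donors/patients).
#' @return A named list (by video id) of `list(video, truth)` pairs.
#' @export
generate_cohort <- function(counts, base_config = synthetic_config(),
                            seed = 1L, abnormal_fraction = NULL) {
  if (length(counts) == 0L || is.null(names(counts)) ||
      !all(names(counts) %in% rhha_conditions())) {
    abort("counts must be named with conditions among healthy/SCD/THAL/HS",
          "slitflow_config_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers", "slitflow_config_error")
  }
  total <- sum(counts)
  if (total == 0L) return(list())
  vseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, total))
  out <- vector("list", total)
  ids <- character(total)
  k <- 0L
  for (cond in names(counts)) {
    for (r in seq_len(counts[[cond]])) {
      k <- k + 1L
      vid <- sprintf("v%02d_%s", k, cond)
      cfg <- synthetic_config(
        frame_size = base_config$frame_size, n_frames = base_config$n_frames,
        fps = base_config$fps, barrier_x = base_config$barrier_x,
        cell_radius_px = base_config$cell_radius_px,
        n_cells = base_config$n_cells,
        velocity_px_per_frame = base_config$velocity_px_per_frame,
        condition = cond,
        abnormal_fraction = if (!is.null(abnormal_fraction)) {
          if (!is.null(names(abnormal_fraction)))
            abnormal_fraction[[cond]] else abnormal_fraction
        } else if (base_config$abnormal_fraction_user) {
          base_config$abnormal_fraction
        } else NULL,
        noise_sigma = base_config$noise_sigma,
        defocus_prob = base_config$defocus_prob,
        seed = vseeds[k], video_id = vid)
      out[[k]] <- generate_video(cfg)
      ids[k] <- vid
    }
  }
  names(out) <- ids
  out
}

#' Cohort manifest
#'
#' @param cohort a list returned by [generate_cohort()].
#' @param paths optional per-video file paths to record.
#' @return A data frame with one row per video: id, condition, cell counts.
#' @export
cohort_manifest <- function(cohort, paths = NA_character_) {
  data.frame(
    video_id = vapply(cohort, function(x) x$video$video_id, character(1)),
    path = paths,
    condition = vapply(cohort, function(x) x$truth$condition, character(1)),
    n_cells = vapply(cohort, function(x) nrow(x$truth$cells), integer(1)),
    n_abnormal = vapply(cohort, function(x)
      sum(x$truth$cells$shape_class == "abnormal"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Shift ground-truth columns after cropping
#'
#' @param truth a `ground_truth` object.
#' @param col_offset number of columns removed on the left of the frame.
#' @return The truth object with centre columns remapped into the cropped
#'   coordinate system.
#' @export
shift_truth <- function(truth, col_offset) {
  truth$trajectory$col <- truth$trajectory$col - col_offset
  truth$cells$start_col <- truth$cells$start_col - col_offset
  truth$barrier_x <- truth$barrier_x - col_offset
  truth
}

#' Write ground truth as JSON
#' @param truth a `ground_truth` object.
#' @param path output file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(condition = truth$condition, barrier_x = truth$barrier_x,
         cells = truth$cells, trajectory = truth$trajectory),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth written by [write_truth()]
#' @param path JSON file path.
#' @return A `ground_truth` object (without the generating config).
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(cells = as.data.frame(x$cells),
                 trajectory = as.data.frame(x$trajectory),
                 condition = x$condition, barrier_x = x$barrier_x,
                 config = NULL),
            class = "ground_truth")
}
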