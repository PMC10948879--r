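#' Configuration of a synthetic two-channel phagocytosis scene
#'
#' Describes a scripted scene: bright, initially static fluorescent aggregate
#' blobs on a dark background in one channel, and low-contrast textured cells
#' performing random walks in the other, with optional acquisition artifacts
#' (global x/y frame shifts, transient Gaussian blur) and scripted
#' phagocytosis events. Defaults mirror the acquisition conditions of the
#' assay this package quantifies: 0.103 um square pixels and one frame every
#' 2 minutes.
#'
#' Coordinates are `(row, col)`, 0-based, with pixel centers at integer
#' coordinates; shifts are `(dx = column offset, dy = row offset)`.
#'
#' @param frame_size square frame side, pixels.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval minutes between frames.
#' @param pixel_size micrometers per pixel.
#' @param n_cells number of cells.
#' @param n_aggregates number of aggregates.
#' @param cell_speed cell step length, px/frame (rendered as integer-lattice
#'   steps of `round(cell_speed)` px so cell appearance translates exactly
#'   between frames).
#' @param shift_schedule list of `c(frame, dx, dy)` global shifts (1-based
#'   frame index; unlisted frames have zero shift).
#' @param blur_schedule list of `c(frame, sigma)` transient Gaussian blurs.
#' @param phagocytosis_events list of `list(id, frame, mode)` with
#'   `mode %in% c("shrink", "jump")`.
#' @param noise_level additive Gaussian noise standard deviation, gray levels.
#' @param rng_seed integer seed; a fixed seed makes the scene bit-identical
#'   across runs.
#' @return A `scene_config` object.
#' @export
scene_config <- function(frame_size = 512L, n_frames = 30L,
                         frame_interval = 2, pixel_size = 0.103,
                         n_cells = 8L, n_aggregates = 12L,
                         cell_speed = 2,
                         shift_schedule = list(), blur_schedule = list(),
                         phagocytosis_events = list(),
                         noise_level = 0.3, rng_seed = 42L) {
  if (frame_size <= 0) stop_config("'frame_size' must be > 0")
  if (n_frames < 2) stop_config("'n_frames' must be >= 2")
  if (pixel_size <= 0) stop_config("'pixel_size' must be > 0")
  check_frame <- function(f, what) {
    if (f < 1 || f > n_frames)
      stop_config(sprintf("%s frame index %d outside [1, %d]", what, f,
                          n_frames))
  }
  for (s in shift_schedule) check_frame(s[[1L]], "shift_schedule")
  for (b in blur_schedule) check_frame(b[[1L]], "blur_schedule")
  for (e in phagocytosis_events) {
    ev <- as_event(e)
    check_frame(ev$frame, "phagocytosis_events")
    if (!ev$mode %in% c("shrink", "jump"))
      stop_config("event mode must be 'shrink' or 'jump'")
    if (ev$id < 1 || ev$id > n_aggregates)
      stop_config("event aggregate id outside [1, n_aggregates]")
  }
  structure(list(frame_size = as.integer(frame_size),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, pixel_size = pixel_size,
                 n_cells = as.integer(n_cells),
                 n_aggregates = as.integer(n_aggregates),
                 cell_speed = cell_speed, shift_schedule = shift_schedule,
                 blur_schedule = blur_schedule,
                 phagocytosis_events = phagocytosis_events,
                 noise_level = noise_level, rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

as_event <- function(e) {
  if (is.list(e)) list(id = as.integer(e[[1L]]), frame = as.integer(e[[2L]]),
                       mode = as.character(e[[3L]]))
  else list(id = as.integer(e[1L]), frame = as.integer(e[2L]),
            mode = as.character(e[3L]))
}

# Gray-level constants of the renderer. Aggregates: bright on dark. Cells:
# zero-mean texture on a mid-gray background, so a global threshold cannot
# separate cells from background (the temporal-coherence module is needed).
SCENE_BG_AGG <- 10
SCENE_FG_AGG <- 230
SCENE_BG_CELL <- 100
SCENE_CELL_TEXTURE_AMP <- 26

render_disk <- function(img, r0, c0, rad, value) {
  n <- nrow(img)
  ri <- max(1, floor(r0 - rad)):min(n, ceiling(r0 + rad) + 1)
  ci <- max(1, floor(c0 - rad)):min(ncol(img), ceiling(c0 + rad) + 1)
  d2 <- outer((ri - 1) - r0, rep(1, length(ci)))^2 +
    outer(rep(1, length(ri)), (ci - 1) - c0)^2
  sub <- img[ri, ci, drop = FALSE]
  sub[d2 <= rad^2] <- value
  img[ri, ci] <- sub
  img
}

disk_pixels <- function(n, r0, c0, rad) {
  ri <- max(1, floor(r0 - rad)):min(n, ceiling(r0 + rad) + 1)
  ci <- max(1, floor(c0 - rad)):min(n, ceiling(c0 + rad) + 1)
  d2 <- outer((ri - 1) - r0, rep(1, length(ci)))^2 +
    outer(rep(1, length(ri)), (ci - 1) - c0)^2
  idx <- which(d2 <= rad^2, arr.ind = TRUE)
  cbind(ri[idx[, 1L]], ci[idx[, 2L]])
}

# Rejection-sample blob centers with pairwise separation, under a patchy
# density field (aggregate deposition on the dish is uneven; the resulting
# large-scale intensity structure is also what anchors the coarsest
# registration level).
sample_positions <- function(n_obj, frame_size, radii, margin, min_gap = 6) {
  nd <- 5L
  dc <- cbind(runif(nd, 0, frame_size), runif(nd, 0, frame_size))
  ds <- runif(nd, frame_size / 6, frame_size / 3)
  dw <- runif(nd, 0.5, 1)
  dens <- function(r, c) {
    v <- 0.15
    for (j in seq_len(nd))
      v <- v + dw[j] * exp(-((r - dc[j, 1])^2 + (c - dc[j, 2])^2) /
                             (2 * ds[j]^2))
    min(v, 1)
  }
  pos <- matrix(NA_real_, n_obj, 2L)
  placed <- 0L
  tries <- 0L
  while (placed < n_obj) {
    tries <- tries + 1L
    if (tries > 20000L)
      stop_config("could not place objects; frame too small for the counts")
    lo <- margin + radii[placed + 1L]
    hi <- frame_size - 1 - margin - radii[placed + 1L]
    if (hi <= lo) stop_config("frame too small for object radius + margin")
    r0 <- runif(1, lo, hi); c0 <- runif(1, lo, hi)
    if (runif(1) > dens(r0, c0)) next
    if (placed > 0L) {
      d <- sqrt((pos[seq_len(placed), 1L] - r0)^2 +
                  (pos[seq_len(placed), 2L] - c0)^2)
      if (any(d < radii[seq_len(placed)] + radii[placed + 1L] + min_gap)) next
    }
    placed <- placed + 1L
    pos[placed, ] <- c(r0, c0)
  }
  pos
}

#' Apply acquisition artifacts to a single frame
#'
#' Mimics the two acquisition faults the quality-control stage must catch:
#' unintended global x/y shaking of the stage (sub-pixel translation warp) and
#' the lens transiently going out of focus (Gaussian blur). A zero shift with
#' zero blur returns the frame unchanged.
#'
#' @param frame numeric matrix.
#' @param shift `c(dx, dy)` translation in pixels (dx = columns, dy = rows).
#' @param blur_sigma Gaussian blur standard deviation in pixels (>= 0).
#' @param fill gray level filling pixels that enter from outside the field
#'   of view (the channel's background level).
#' @return The degraded frame.
#' @export
apply_artifacts <- function(frame, shift = c(0, 0), blur_sigma = 0,
                            fill = 0) {
  assert_matrix(frame)
  if (blur_sigma < 0) stop_config("'blur_sigma' must be >= 0")
  out <- frame
  if (any(shift != 0))
    out <- cpp_warp_translate(out, shift[1L], shift[2L], fill)
  if (blur_sigma > 0)
    out <- gaussian_smooth(out, sigma = blur_sigma)
  out
}

#' Generate a synthetic two-channel scene with ground truth
#'
#' Renders the aggregate channel (bright disks, static until scripted events)
#' and the cell channel (textured random-walking blobs), applies the scripted
#' shift and blur artifacts, adds acquisition noise, and returns the full
#' ground truth: per-frame true shifts and blur flags, per-frame instance
#' masks and feature tables for both channels (in reference, i.e. unshifted,
#' coordinates), and the scripted event list.
#'
#' Scripted events: `"shrink"` halves the aggregate's area in one inter-frame
#' step, then decays it to zero over subsequent frames; `"jump"` halves the
#' area and displaces the centroid by ~9 px in one step. Both therefore lose
#' at least 50% of their area at the event frame.
#'
#' @param config a [scene_config()].
#' @return A list with elements `aggregates` and `cells` (two
#'   [frame_stack()]s, 8-bit) and `truth` (a list: `shifts` data frame,
#'   `blur` data frame, `aggregate_masks`/`cell_masks` lists of integer label
#'   matrices, `aggregate_tables`/`cell_tables` per-frame feature data frames,
#'   `events` data frame).
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config")) stop_config("not a scene_config")
  with_seed(config$rng_seed, generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  n <- config$frame_size
  nf <- config$n_frames
  max_shift <- if (length(config$shift_schedule))
    max(vapply(config$shift_schedule, function(s) max(abs(s[2:3])), 0)) else 0

  # --- aggregates: radii, patchy static positions -------------------------
  na <- config$n_aggregates
  agg_rad0 <- if (na) runif(na, 4, 10) else numeric(0)
  agg_pos <- if (na)
    sample_positions(na, n, agg_rad0, margin = max_shift + 4)
  else matrix(0, 0, 2)

  # per-frame radius/position schedule driven by scripted events
  events <- lapply(config$phagocytosis_events, as_event)
  agg_rad <- matrix(rep(agg_rad0, each = nf), nf, na)
  agg_r <- matrix(rep(agg_pos[, 1L], each = nf), nf, na)
  agg_c <- matrix(rep(agg_pos[, 2L], each = nf), nf, na)
  for (ev in events) {
    f0 <- ev$frame
    id <- ev$id
    # area -> ~45% of initial at the event frame (a robust halving once
    # discretized to pixels), then geometric decay to zero
    shrink <- 0.95 / sqrt(2)
    agg_rad[f0:nf, id] <- agg_rad[f0, id] * shrink
    if (f0 < nf) {
      k <- seq.int(f0 + 1L, nf)
      agg_rad[k, id] <- agg_rad[f0, id] * 0.72^(seq_along(k))
    }
    if (ev$mode == "jump" && na) {
      # displace towards the frame center by ~9 px (>= the 7 px rule)
      dirv <- c(n / 2 - agg_r[f0, id], n / 2 - agg_c[f0, id])
      dirv <- dirv / max(sqrt(sum(dirv^2)), 1e-9)
      agg_r[f0:nf, id] <- agg_r[f0, id] + 9 * dirv[1L]
      agg_c[f0:nf, id] <- agg_c[f0, id] + 9 * dirv[2L]
    }
  }
  agg_rad[agg_rad^2 * pi < 3] <- 0  # below ~3 px the aggregate is gone

  # --- cells: radii, positions, random walks ------------------------------
  ncl <- config$n_cells
  cell_rad <- if (ncl) runif(ncl, 14, 22) else numeric(0)
  cell_pos0 <- if (ncl)
    sample_positions(ncl, n, cell_rad, margin = max_shift + 4, min_gap = 10)
  else matrix(0, 0, 2)
  cell_r <- matrix(0, nf, ncl)
  cell_c <- matrix(0, nf, ncl)
  if (ncl) {
    # integer-lattice random walk (4 compass directions, constant step):
    # the cell's appearance translates exactly between frames, so frame
    # sharpness statistics are motion-invariant
    cell_r[1L, ] <- round(cell_pos0[, 1L])
    cell_c[1L, ] <- round(cell_pos0[, 2L])
    step <- max(1, round(config$cell_speed))
    lo <- ceiling(cell_rad + 2)
    hi <- floor(n - 1 - cell_rad - 2)
    for (t in seq_len(nf - 1L)) {
      dir <- sample.int(4L, ncl, replace = TRUE)
      rr <- cell_r[t, ] + step * c(-1, 0, 1, 0)[dir]
      cc <- cell_c[t, ] + step * c(0, 1, 0, -1)[dir]
      out_of_bounds <- rr < lo | rr > hi | cc < lo | cc > hi
      rr[out_of_bounds] <- cell_r[t, out_of_bounds]  # bounce: stay put
      cc[out_of_bounds] <- cell_c[t, out_of_bounds]
      cell_r[t + 1L, ] <- rr
      cell_c[t + 1L, ] <- cc
    }
    # per-cell frozen texture field: band-limited noise, zero mean
    texture <- lapply(seq_len(ncl), function(i) {
      side <- 2L * ceiling(cell_rad[i]) + 7L
      tx <- matrix(rnorm(side * side), side, side)
      tx <- as.matrix(EBImage::gblur(tx, sigma = 1.2))
      tx / max(sd(tx), 1e-9)
    })
  }

  shift_map <- matrix(0, nf, 2L)
  for (s in config$shift_schedule)
    shift_map[s[[1L]], ] <- c(s[[2L]], s[[3L]])
  blur_map <- numeric(nf)
  for (b in config$blur_schedule) blur_map[b[[1L]]] <- b[[2L]]

  agg_frames <- vector("list", nf)
  cell_frames <- vector("list", nf)
  agg_masks <- vector("list", nf)
  cell_masks <- vector("list", nf)
  agg_tabs <- vector("list", nf)
  cell_tabs <- vector("list", nf)

  # pre-draw per-frame noise AFTER geometry so object layout is stable under
  # noise_level changes
  for (t in seq_len(nf)) {
    af <- matrix(SCENE_BG_AGG, n, n)
    am <- matrix(0L, n, n)
    rows <- list()
    for (i in seq_len(na)) {
      if (agg_rad[t, i] <= 0) next
      px <- disk_pixels(n, agg_r[t, i], agg_c[t, i], agg_rad[t, i])
      if (!nrow(px)) next
      af[px] <- SCENE_FG_AGG
      am[px] <- i
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t, id = i, area_px = nrow(px),
        row = mean(px[, 1L] - 1), col = mean(px[, 2L] - 1))
    }
    agg_tabs[[t]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(frame = integer(0), id = integer(0), area_px = integer(0),
                 row = numeric(0), col = numeric(0))

    cf <- matrix(SCENE_BG_CELL, n, n)
    cm <- matrix(0L, n, n)
    crows <- list()
    for (i in seq_len(ncl)) {
      px <- disk_pixels(n, cell_r[t, i], cell_c[t, i], cell_rad[i])
      if (!nrow(px)) next
      tx <- texture[[i]]
      # bilinear texture lookup at the exact sub-pixel offset from the cell
      # center, so appearance translates continuously with the cell and the
      # frame's high-frequency content is (near) motion-invariant
      tr <- (px[, 1L] - 1) - cell_r[t, i] + (nrow(tx) + 1) / 2
      tc <- (px[, 2L] - 1) - cell_c[t, i] + (ncol(tx) + 1) / 2
      tr <- pmin(pmax(tr, 1), nrow(tx) - 1e-9)
      tc <- pmin(pmax(tc, 1), ncol(tx) - 1e-9)
      r0 <- floor(tr); c0 <- floor(tc)
      fr <- tr - r0; fc <- tc - c0
      r1 <- pmin(r0 + 1, nrow(tx)); c1 <- pmin(c0 + 1, ncol(tx))
      val <- (1 - fr) * ((1 - fc) * tx[cbind(r0, c0)] + fc * tx[cbind(r0, c1)]) +
        fr * ((1 - fc) * tx[cbind(r1, c0)] + fc * tx[cbind(r1, c1)])
      # taper the texture over the outer ~3 px of the cell so rim pixels
      # entering/leaving the disk carry vanishing contrast (keeps the
      # frame's sharpness statistic motion-invariant)
      dctr <- sqrt(((px[, 1L] - 1) - cell_r[t, i])^2 +
                     ((px[, 2L] - 1) - cell_c[t, i])^2)
      taper <- pmin(pmax((cell_rad[i] - dctr) / 3, 0), 1)
      cf[px] <- SCENE_BG_CELL + SCENE_CELL_TEXTURE_AMP * val * taper
      cm[px] <- i
      crows[[length(crows) + 1L]] <- data.frame(
        frame = t, id = i, area_px = nrow(px),
        row = mean(px[, 1L] - 1), col = mean(px[, 2L] - 1))
    }
    cell_tabs[[t]] <- if (length(crows)) do.call(rbind, crows) else
      data.frame(frame = integer(0), id = integer(0), area_px = integer(0),
                 row = numeric(0), col = numeric(0))

    # stage shake moves the (smooth) scene content; the additive term models
    # scene-intrinsic high-frequency signal, so it enters before the optical
    # blur of a defocus episode -- as on real data, where genuine image
    # content, not sensor noise, carries the sharpness statistic
    af <- apply_artifacts(af, shift_map[t, ], 0, fill = SCENE_BG_AGG)
    cf <- apply_artifacts(cf, shift_map[t, ], 0, fill = SCENE_BG_CELL)
    if (config$noise_level > 0) {
      af <- af + matrix(rnorm(n * n, 0, config$noise_level), n, n)
      cf <- cf + matrix(rnorm(n * n, 0, config$noise_level), n, n)
    }
    if (blur_map[t] > 0) {
      af <- apply_artifacts(af, c(0, 0), blur_map[t])
      cf <- apply_artifacts(cf, c(0, 0), blur_map[t])
    }
    agg_frames[[t]] <- pmin(pmax(round(af), 0), 255)
    cell_frames[[t]] <- pmin(pmax(round(cf), 0), 255)
    agg_masks[[t]] <- am
    cell_masks[[t]] <- cm
  }

  truth <- list(
    shifts = data.frame(frame = seq_len(nf), dx = shift_map[, 1L],
                        dy = shift_map[, 2L]),
    blur = data.frame(frame = seq_len(nf), sigma = blur_map,
                      blurred = blur_map > 0),
    aggregate_masks = agg_masks, cell_masks = cell_masks,
    aggregate_tables = do.call(rbind, agg_tabs),
    cell_tables = do.call(rbind, cell_tabs),
    events = if (length(events)) data.frame(
      id = vapply(events, `[[`, 0L, "id"),
      frame = vapply(events, `[[`, 0L, "frame"),
      mode = vapply(events, `[[`, "", "mode")) else
        data.frame(id = integer(0), frame = integer(0), mode = character(0)))

  list(
    aggregates = frame_stack_memory(agg_frames, bit_depth = 8L,
                                    pixel_size = config$pixel_size,
                                    frame_interval = config$frame_interval),
    cells = frame_stack_memory(cell_frames, bit_depth = 8L,
                               pixel_size = config$pixel_size,
                               frame_interval = config$frame_interval),
    truth = truth)
}

#' Write a synthetic scene to disk
#'
#' Writes the two channels as per-channel frame directories of 8-bit
#' single-page TIFF files, the instance masks as 16-bit TIFF, and the ground
#' truth (shifts, blur schedule, events, per-frame feature tables) as
#' `ground_truth.json`.
#'
#' @param scene result of [generate_scene()].
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(scene$aggregates, file.path(dir, "aggregates"))
  write_stack(scene$cells, file.path(dir, "cells"))
  for (ch in c("aggregate_masks", "cell_masks")) {
    mdir <- file.path(dir, ch)
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_along(scene$truth[[ch]]))
      tiff::writeTIFF(scene$truth[[ch]][[i]] / 65535,
                      file.path(mdir, sprintf("t%04d.tif", i - 1L)),
                      bits.per.sample = 16L)
  }
  gt <- scene$truth[c("shifts", "blur", "aggregate_tables", "cell_tables",
                      "events")]
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}

#' Synthetic aggregate-like frame for registration validation
#'
#' One gray-level frame of bright Gaussian blobs on a dark background with
#' patchy large-scale blob density, emulating a fluorescent-aggregate field
#' at the start of an assay. Used by the drift-correction validation
#' protocol: warp it by known random translations and check recovery.
#'
#' @param frame_size square side, px.
#' @param n_blobs number of Gaussian blobs.
#' @param noise_sd additive noise standard deviation (intensity units of an
#'   image in `[0, ~1]`).
#' @param seed RNG seed.
#' @return Numeric matrix.
#' @export
registration_test_frame <- function(frame_size = 2048L, n_blobs = 1000L,
                                    noise_sd = 0.01, seed = 11L) {
  with_seed(seed, {
    n <- frame_size
    nd <- 3L
    dc <- cbind(runif(nd, n * 0.2, n * 0.8), runif(nd, n * 0.2, n * 0.8))
    ds <- runif(nd, n / 4, n / 2.8)
    dw <- runif(nd, 0.5, 1)
    img <- matrix(0, n, n)
    placed <- 0L
    while (placed < n_blobs) {
      r0 <- runif(1, 40, n - 40)
      c0 <- runif(1, 40, n - 40)
      v <- 0.1
      for (j in seq_len(nd))
        v <- v + dw[j] * exp(-((r0 - dc[j, 1])^2 + (c0 - dc[j, 2])^2) /
                               (2 * ds[j]^2))
      if (runif(1) > min(v, 1)) next
      placed <- placed + 1L
      s <- runif(1, 3, 15)
      a <- runif(1, 0.4, 1)
      ri <- max(1, floor(r0 - 4 * s)):min(n, ceiling(r0 + 4 * s))
      ci <- max(1, floor(c0 - 4 * s)):min(n, ceiling(c0 + 4 * s))
      img[ri, ci] <- img[ri, ci] +
        a * exp(-(outer((ri - 1) - r0, rep(1, length(ci)))^2 +
                    outer(rep(1, length(ri)), (ci - 1) - c0)^2) / (2 * s^2))
    }
    img + matrix(rnorm(n * n, 0, noise_sd), n, n)
  })
}

#' Shift-recovery experiment for the cascade registration
#'
#' Draws independent x/y translations uniformly within `±shift_bound` px,
#' warps a synthetic aggregate-like frame by each, registers every warped
#' copy back with [cecc_register()], and reports per-axis absolute errors.
#'
#' @param image reference frame (default [registration_test_frame()]).
#' @param n_shifts number of random translations.
#' @param shift_bound per-axis bound, px.
#' @param schedule a [cascade_schedule()].
#' @param max_iter,eps ECC termination settings.
#' @param seed RNG seed for the shift draws.
#' @return Data frame: true and estimated dx/dy, per-axis absolute errors,
#'   convergence flag.
#' @export
registration_shift_experiment <- function(image = registration_test_frame(),
                                          n_shifts = 20L, shift_bound = 400,
                                          schedule = cascade_schedule(),
                                          max_iter = 1000L, eps = 1e-4,
                                          seed = 1L) {
  pyr <- smooth_pyramid(image, schedule)
  shifts <- with_seed(seed, cbind(runif(n_shifts, -shift_bound, shift_bound),
                                  runif(n_shifts, -shift_bound, shift_bound)))
  rows <- lapply(seq_len(n_shifts), function(i) {
    mov <- cpp_warp_translate(image, shifts[i, 1L], shifts[i, 2L], 0)
    tr <- cecc_register(image, mov, schedule, max_iter = max_iter, eps = eps,
                        reference_pyramid = pyr)
    data.frame(dx_true = shifts[i, 1L], dy_true = shifts[i, 2L],
               dx_est = tr$shift[["dx"]], dy_est = tr$shift[["dy"]],
               err_x = abs(tr$shift[["dx"]] - shifts[i, 1L]),
               err_y = abs(tr$shift[["dy"]] - shifts[i, 2L]),
               converged = tr$converged)
  })
  do.call(rbind, rows)
}
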