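#' Gaussian sigma for a given smoothing kernel size
#'
#' The standard deviation paired with an odd Gaussian kernel size in the
#' cascade registration schedule: `0.3 * ((kernel_size - 1) * 0.5 - 1) + 0.8`.
#' A 513-px kernel corresponds to a sigma of about 77.3 px and a 257-px kernel
#' to about 38.9 px.
#'
#' @param kernel_size odd positive integer.
#' @return Sigma in pixels.
#' @export
gaussian_sigma <- function(kernel_size) {
  if (any(kernel_size < 1) || any(kernel_size %% 2 != 1))
    stop_config("'kernel_size' must be an odd integer >= 1")
  0.3 * ((kernel_size - 1) * 0.5 - 1) + 0.8
}

#' Cascade schedule for coarse-to-fine ECC registration
#'
#' An ordered list of Gaussian kernel sizes, strictly decreasing, with the
#' final level running on the raw (unsmoothed) frames. The default 5-level
#' schedule starts at 513 px, then roughly halves the kernel at each level
#' (513, 257, 129, 65, raw); per-level sigmas come from [gaussian_sigma()].
#'
#' @param n_levels number of cascade levels (>= 1); the last level is raw.
#' @param base_kernel kernel size of the coarsest level, odd.
#' @return A `cascade_schedule` object: data frame of `level`, `kernel_size`
#'   (NA for the raw level) and `sigma`.
#' @export
cascade_schedule <- function(n_levels = 5L, base_kernel = 513L) {
  if (n_levels < 1) stop_config("'n_levels' must be >= 1")
  ks <- integer(0)
  k <- as.integer(base_kernel)
  for (i in seq_len(n_levels - 1L)) {
    ks <- c(ks, k)
    k <- (k - 1L) %/% 2L + 1L  # halving keeps sizes odd: 513 -> 257 -> 129
  }
  if (any(diff(ks) >= 0)) stop_config("kernel sizes must strictly decrease")
  out <- data.frame(level = seq_len(n_levels),
                    kernel_size = c(ks, NA_integer_),
                    sigma = c(if (length(ks)) gaussian_sigma(ks) else numeric(0),
                              NA_real_))
  class(out) <- c("cascade_schedule", "data.frame")
  out
}

#' Gaussian smoothing with an explicit kernel size
#'
#' Separable Gaussian convolution (FFT-backed) with either an explicit odd
#' `kernel_size` (sigma from [gaussian_sigma()]) or an explicit `sigma`
#' (kernel size `2 * ceiling(3 * sigma) + 1`). Zero-padded boundary.
#'
#' @param frame numeric matrix.
#' @param kernel_size odd kernel size, or NULL.
#' @param sigma Gaussian sigma in px, or NULL.
#' @return Smoothed frame.
#' @export
gaussian_smooth <- function(frame, kernel_size = NULL, sigma = NULL) {
  assert_matrix(frame)
  if (is.null(kernel_size) && is.null(sigma))
    stop_config("give 'kernel_size' or 'sigma'")
  if (is.null(sigma)) sigma <- gaussian_sigma(kernel_size)
  if (is.null(kernel_size)) kernel_size <- 2L * ceiling(3 * sigma) + 1L
  half <- (kernel_size - 1L) / 2
  k1 <- dnorm(seq(-half, half), sd = sigma)
  k1 <- k1 / sum(k1)
  if (kernel_size <= 129L) {
    cpp_sep_convolve(frame, k1)
  } else {
    k1 <- matrix(k1, ncol = 1L)
    out <- EBImage::filter2(frame, k1, boundary = 0)
    as.matrix(EBImage::filter2(out, t(k1), boundary = 0))
  }
}

# Heavy smoothing followed by grid decimation: anti-alias with a small
# Gaussian (sigma = d/2), keep every d-th pixel, then apply the remaining
# smoothing at the decimated resolution so the total blur equals `sigma`
# (variances add). Numerically equivalent relief for the coarse ECC levels at
# a fraction of the cost; sub-pixel precision is owned by the final raw level.
smooth_decimate <- function(frame, sigma, d) {
  if (d <= 1L) return(gaussian_smooth(frame, sigma = sigma))
  saa <- d / 2
  out <- gaussian_smooth(frame, sigma = saa)
  out <- out[seq(1L, nrow(out), by = d), seq(1L, ncol(out), by = d)]
  srem <- sqrt(sigma^2 - saa^2) / d
  gaussian_smooth(out, sigma = srem)
}

# Decimation factor for a cascade level: keep the effective (decimated) sigma
# at >= 6 px, capped at 8x.
decimation_factor <- function(sigma) {
  if (is.na(sigma) || sigma < 12) return(1L)
  as.integer(2^min(3, floor(log2(sigma / 6))))
}

# Integer-shift initialization by zero-mean FFT cross-correlation, searched
# over |shift| <= 45% of the frame side. Used only as a fallback when the
# coarsest ECC level ends with a poor correlation (wrong basin).
xcorr_init <- function(reference, moving) {
  n1 <- nrow(reference); n2 <- ncol(reference)
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  sh_r <- c(0:(n1 - 1)); sh_r[sh_r > n1 / 2] <- sh_r[sh_r > n1 / 2] - n1
  sh_c <- c(0:(n2 - 1)); sh_c[sh_c > n2 / 2] <- sh_c[sh_c > n2 / 2] - n2
  ok_r <- abs(sh_r) <= 0.45 * n1
  ok_c <- abs(sh_c) <= 0.45 * n2
  cc[!ok_r, ] <- -Inf
  cc[, !ok_c] <- -Inf
  k <- arrayInd(which.max(cc), dim(cc))
  # cc(i, j) peaks where moving(r + dr, c + dc) ~ reference; our shift
  # convention is moving = reference translated by (dx, dy)
  c(dx = -sh_c[k[2L]], dy = -sh_r[k[1L]])
}

#' Single-level ECC translation estimation
#'
#' Iteratively maximizes the enhanced correlation coefficient between the
#' reference frame and a translated sampling of the moving frame, starting
#' from `init`. Returns the estimated `(dx, dy)` shift of the moving frame
#' relative to the reference (sub-pixel) and convergence information.
#' Termination: correlation increment below `eps`, or `max_iter` iterations.
#'
#' @param reference,moving same-shape numeric matrices.
#' @param init starting translation `c(dx, dy)`.
#' @param max_iter iteration cap (default 1000).
#' @param eps correlation-increment termination threshold (default 1e-4).
#' @return List: `shift` (`c(dx, dy)`), `rho` (final correlation),
#'   `iterations`, `converged`, `status`.
#' @export
ecc_translation <- function(reference, moving, init = c(0, 0),
                            max_iter = 1000L, eps = 1e-4) {
  assert_matrix(reference)
  assert_matrix(moving)
  if (!all(is.finite(init))) stop_config("'init' must be finite")
  if (any(abs(init) >= dim(reference)))
    stop_registration("initial shift leaves no frame overlap")
  res <- cpp_ecc_translation(reference, moving, init[1L], init[2L],
                             as.integer(max_iter), eps)
  if (res$status == "no_overlap")
    stop_registration("estimated shift leaves no frame overlap")
  list(shift = c(dx = res$dx, dy = res$dy), rho = res$rho,
       iterations = res$iterations, converged = res$converged,
       status = res$status)
}

#' Cascade ECC registration of one frame pair
#'
#' Runs [ecc_translation()] over the cascade: the coarsest level operates on
#' frames smoothed with the largest Gaussian kernel and starts from `(0, 0)`;
#' each subsequent level re-estimates on less-smoothed frames, initialized
#' with the previous level's translation; the final level uses the raw
#' frames. Both frames are smoothed identically at every level. All
#' intermediate per-level translations are recorded for traceability.
#'
#' @param reference,moving same-shape numeric matrices.
#' @param schedule a [cascade_schedule()].
#' @param max_iter,eps per-level ECC termination settings.
#' @param reference_pyramid optional pre-smoothed reference frames (from
#'   [smooth_pyramid()]) reused across moving frames of the same stack.
#' @return A `transform_record`: list with `shift` (final `c(dx, dy)`),
#'   `levels` (data frame of per-level dx, dy, rho, iterations, converged),
#'   `converged`, `failed_level` (NA when all levels converge).
#' @export
cecc_register <- function(reference, moving, schedule = cascade_schedule(),
                          max_iter = 1000L, eps = 1e-4,
                          reference_pyramid = NULL) {
  if (is.null(reference_pyramid))
    reference_pyramid <- smooth_pyramid(reference, schedule)
  p <- c(0, 0)
  lv <- vector("list", nrow(schedule))
  failed <- NA_integer_
  for (l in seq_len(nrow(schedule))) {
    sg <- schedule$sigma[l]
    d <- decimation_factor(sg)
    mov_l <- if (is.na(schedule$kernel_size[l])) moving
             else smooth_decimate(moving, sg, d)
    ref_l <- reference_pyramid[[l]]
    run <- function(init) tryCatch(
      ecc_translation(ref_l, mov_l, init = init,
                      max_iter = max_iter, eps = eps),
      phagoquant_registration_error = function(e) NULL)
    res <- run(p / d)
    if (l == 1L && (is.null(res) || res$rho < 0.98)) {
      # wrong basin at the coarsest level: re-initialize from the integer
      # cross-correlation peak and keep the better of the two runs
      res2 <- run(xcorr_init(ref_l, mov_l))
      if (!is.null(res2) && (is.null(res) || res2$rho > res$rho)) res <- res2
    }
    if (is.null(res)) {
      if (is.na(failed)) failed <- l
      lv[[l]] <- data.frame(level = l, dx = p[1L], dy = p[2L], rho = NA_real_,
                            iterations = 0L, converged = FALSE)
      next
    }
    if (!res$converged && is.na(failed) && res$status %in%
          c("degenerate", "uncorrelated", "diverged"))
      failed <- l
    p <- unname(res$shift) * d
    lv[[l]] <- data.frame(level = l, dx = p[1L], dy = p[2L], rho = res$rho,
                          iterations = res$iterations,
                          converged = res$converged)
  }
  levels <- do.call(rbind, lv)
  structure(list(shift = c(dx = p[1L], dy = p[2L]), levels = levels,
                 converged = all(levels$converged), failed_level = failed),
            class = "transform_record")
}

#' Pre-smooth a reference frame at every cascade level
#'
#' Coarse levels (sigma >= 12 px) are decimated after smoothing; the last
#' level is the raw frame.
#'
#' @param frame numeric matrix.
#' @param schedule a [cascade_schedule()].
#' @return List of smoothed frames, one per level (raw for the last).
#' @export
smooth_pyramid <- function(frame, schedule = cascade_schedule()) {
  lapply(seq_len(nrow(schedule)), function(l) {
    ks <- schedule$kernel_size[l]
    if (is.na(ks)) frame
    else smooth_decimate(frame, schedule$sigma[l],
                         decimation_factor(schedule$sigma[l]))
  })
}

#' Apply a sub-pixel translation to a frame
#'
#' Bilinear translation warp; pixels moving in from outside the field of view
#' are filled with the dark background value 0.
#'
#' @param frame numeric matrix.
#' @param shift `c(dx, dy)` in pixels.
#' @return Warped frame.
#' @export
apply_translation <- function(frame, shift) {
  assert_matrix(frame)
  if (!all(is.finite(shift))) stop_config("'shift' must be finite")
  if (all(shift == 0)) return(frame)
  cpp_warp_translate(frame, shift[1L], shift[2L], 0)
}

#' Register a full frame stack to its first frame
#'
#' Frame 1 is the reference; every later frame is registered to it with
#' [cecc_register()] and warped back by the estimated shift. Per-frame
#' failures are recorded and flagged; the pipeline continues on the remaining
#' frames. The estimated translations are the ones later applied to the cell
#' channel and to cell centroids.
#'
#' @param stack a [frame_stack()] (aggregate channel).
#' @param schedule a [cascade_schedule()].
#' @param max_iter,eps ECC termination settings.
#' @return List: `aligned` (a lazy [frame_stack()] of registered frames) and
#'   `records` (data frame: frame, dx, dy, rho, converged, failed_level, plus
#'   a `level_trace` JSON string per frame).
#' @export
register_stack <- function(stack, schedule = cascade_schedule(),
                           max_iter = 1000L, eps = 1e-4) {
  if (stack$n_frames < 2) stop_config("need at least 2 frames")
  ref <- get_frame(stack, 1L)
  pyr <- smooth_pyramid(ref, schedule)
  recs <- vector("list", stack$n_frames)
  recs[[1L]] <- data.frame(frame = 1L, dx = 0, dy = 0, rho = 1,
                           converged = TRUE, failed_level = NA_integer_,
                           level_trace = "[]")
  for (i in seq.int(2L, stack$n_frames)) {
    tr <- cecc_register(ref, get_frame(stack, i), schedule,
                        max_iter = max_iter, eps = eps,
                        reference_pyramid = pyr)
    recs[[i]] <- data.frame(
      frame = i, dx = tr$shift[["dx"]], dy = tr$shift[["dy"]],
      rho = tail(tr$levels$rho, 1L), converged = tr$converged,
      failed_level = tr$failed_level,
      level_trace = as.character(jsonlite::toJSON(tr$levels, digits = NA)))
  }
  records <- do.call(rbind, recs)
  shifts <- records[, c("dx", "dy")]
  aligned <- stack_map_indexed(stack, function(frame, i)
    apply_translation(frame, -as.numeric(shifts[i, ])))
  list(aligned = aligned, records = records)
}

stack_map_indexed <- function(stack, f) {
  frame_stack(function(i) f(get_frame(stack, i), i), stack$n_frames,
              stack$frame_size, bit_depth = stack$bit_depth,
              pixel_size = stack$pixel_size,
              frame_interval = stack$frame_interval)
}

#' Write registration records to CSV
#'
#' @param records data frame from [register_stack()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_registration <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
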