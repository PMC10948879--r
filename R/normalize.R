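#' Global normalization parameters from a reference frame
#'
#' Intensity percentiles of the sequence's first frame are the global
#' normalization baseline: 0.5% and 99.5% for the aggregate channel (all
#' aggregates are present and un-phagocytosed at the start, and the clip
#' suppresses outlier intensities), 0% and 100% for the cell channel. For the
#' cell channel a Gaussian (mean, sd) is additionally fitted to the
#' globally-rescaled reference intensities, as the target distribution of the
#' per-frame local histogram matching.
#'
#' Percentiles use the inverse-empirical-CDF definition
#' (`stats::quantile(type = 1)`).
#'
#' @param reference_frame numeric matrix (typically the first frame).
#' @param channel `"aggregate"` or `"cell"`.
#' @return A `normalization_params` object: list with `channel`,
#'   `percentiles` (ranks), `lo`, `hi` (intensities) and, for cells,
#'   `target_mean`/`target_sd` on the rescaled `[0, 1]` scale.
#' @export
compute_global_params <- function(reference_frame,
                                  channel = c("aggregate", "cell")) {
  assert_matrix(reference_frame)
  channel <- match.arg(channel)
  pr <- if (channel == "aggregate") c(0.5, 99.5) else c(0, 100)
  q <- unname(quantile(reference_frame, pr / 100, type = 1, names = FALSE))
  if (q[1L] == q[2L])
    stop_degenerate("constant reference frame: lo == hi percentile")
  out <- list(channel = channel, percentiles = pr, lo = q[1L], hi = q[2L],
              target_mean = NA_real_, target_sd = NA_real_)
  if (channel == "cell") {
    r <- (reference_frame - q[1L]) / (q[2L] - q[1L])
    r <- pmin(pmax(r, 0), 1)
    out$target_mean <- mean(r)
    out$target_sd <- sd(as.vector(r))
  }
  structure(out, class = "normalization_params")
}

#' Rescale a frame with global percentile parameters
#'
#' Affine map `(x - lo) / (hi - lo)` clipped to `[0, 1]`; monotone
#' non-decreasing in the input intensity.
#'
#' @param frame numeric matrix.
#' @param params a [compute_global_params()] result (or any list with
#'   `lo`/`hi`).
#' @return Frame in `[0, 1]`.
#' @export
rescale_with_percentiles <- function(frame, params) {
  assert_matrix(frame)
  if (params$hi == params$lo)
    stop_degenerate("degenerate normalization: hi == lo")
  pmin(pmax((frame - params$lo) / (params$hi - params$lo), 0), 1)
}

#' Match a frame's histogram to a truncated normal distribution
#'
#' Local (per-frame) normalization of the cell channel: pixel intensities are
#' mapped through their empirical CDF onto the quantile function of a normal
#' distribution with the given mean and standard deviation, truncated to
#' `[0, 1]`. Rank order is preserved; equal input intensities map to equal
#' outputs.
#'
#' @param frame numeric matrix with values in `[0, 1]`.
#' @param target_mean,target_sd parameters of the target normal (on the
#'   `[0, 1]` scale), typically from [compute_global_params()].
#' @return Frame in `[0, 1]` whose empirical distribution approximates the
#'   truncated normal.
#' @export
match_histogram_to_normal <- function(frame, target_mean, target_sd) {
  assert_matrix(frame)
  if (is.na(target_sd) || target_sd <= 0)
    stop_config("'target_sd' must be > 0")
  x <- as.vector(frame)
  # mid-rank plotting positions; ties share a rank, hence an output value
  u <- (rank(x, ties.method = "average") - 0.5) / length(x)
  pa <- pnorm(0, target_mean, target_sd)
  pb <- pnorm(1, target_mean, target_sd)
  y <- qnorm(pa + u * (pb - pa), target_mean, target_sd)
  matrix(pmin(pmax(y, 0), 1), nrow(frame), ncol(frame))
}

#' Convert a 16-bit frame to 8 bits with a fidelity report
#'
#' The frame is assumed to already use the full 16-bit range (rescale first).
#' Conversion is round-half-to-even of `x / 65535 * 255`. Fidelity (MSE,
#' PSNR in dB, SSIM) is measured between the 16-bit frame divided by 2^16 and
#' the 8-bit frame divided by 2^8, i.e. both on a common `[0, 1)` scale.
#'
#' @param frame numeric matrix with integer values in `[0, 65535]`.
#' @return List: `frame8` (values in 0..255) and `fidelity` (list with
#'   `mse`, `psnr`, `ssim`).
#' @export
convert_16_to_8 <- function(frame) {
  assert_matrix(frame)
  frame8 <- round(frame / 65535 * 255)  # round() is round-half-to-even
  a <- frame / 2^16
  b <- frame8 / 2^8
  mse <- mean((a - b)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(1 / mse)
  list(frame8 = frame8,
       fidelity = list(mse = mse, psnr = psnr, ssim = ssim(a, b)))
}

#' Structural similarity index between two frames
#'
#' Standard single-scale SSIM with an 11x11 Gaussian window (sigma 1.5),
#' stabilizers K1 = 0.01, K2 = 0.03, and dynamic range `L`.
#'
#' @param a,b numeric matrices on a common scale.
#' @param L dynamic range of the data (1 for images in `[0, 1]`).
#' @return Mean SSIM over the frame.
#' @export
ssim <- function(a, b, L = 1) {
  if (!identical(dim(a), dim(b))) stop_config("frames must share a shape")
  k <- dnorm(seq(-5, 5), sd = 1.5)
  k <- k / sum(k)
  w <- function(x) cpp_sep_convolve(x, k)
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  mu_a <- w(a); mu_b <- w(b)
  va <- w(a * a) - mu_a^2
  vb <- w(b * b) - mu_b^2
  cab <- w(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(s)
}

#' Downscale a frame to half its side length
#'
#' Anti-aliased 2x2 block averaging (e.g. 2048 x 2048 to 1024 x 1024).
#'
#' @param frame numeric matrix with even side lengths.
#' @return Frame at half resolution.
#' @export
resize_half <- function(frame) {
  assert_matrix(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr %% 2L || nc %% 2L) stop_config("frame sides must be even")
  (frame[seq(1L, nr, 2L), seq(1L, nc, 2L)] +
     frame[seq(2L, nr, 2L), seq(1L, nc, 2L)] +
     frame[seq(1L, nr, 2L), seq(2L, nc, 2L)] +
     frame[seq(2L, nr, 2L), seq(2L, nc, 2L)]) / 4
}

#' Normalize a frame stack (global + local), lazily
#'
#' Computes [compute_global_params()] on the first frame, then derives a lazy
#' stack whose frames are globally percentile-rescaled to `[0, 1]` and, for
#' the cell channel, locally histogram-matched to the reference normal
#' distribution. Optionally halves the resolution. The delayed-reading
#' contract is preserved: frames are normalized on access.
#'
#' @param stack a [frame_stack()].
#' @param channel `"aggregate"` or `"cell"`.
#' @param resize logical; halve the side length after normalization.
#' @return List: `stack` (lazy normalized stack, values in `[0, 1]`,
#'   `bit_depth` 8 nominal) and `params`.
#' @export
normalize_stack <- function(stack, channel = c("aggregate", "cell"),
                            resize = FALSE) {
  channel <- match.arg(channel)
  params <- compute_global_params(get_frame(stack, 1L), channel)
  f <- function(frame) {
    out <- rescale_with_percentiles(frame, params)
    if (channel == "cell")
      out <- match_histogram_to_normal(out, params$target_mean,
                                       params$target_sd)
    if (resize) out <- resize_half(out)
    out
  }
  size <- if (resize) stack$frame_size %/% 2L else stack$frame_size
  ps <- if (resize) stack$pixel_size * 2 else stack$pixel_size
  out <- stack_map(stack, f, frame_size = size)
  out$pixel_size <- ps
  out$unit_scale <- TRUE  # frames live in [0, 1]; written to disk as 8-bit
  list(stack = out, params = params)
}
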