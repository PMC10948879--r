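#' Quality-control parameters
#'
#' @param eps_blur relative-difference threshold of the blur rule, in
#'   `[0, 1]` (default 0.01).
#' @param B recovery look-ahead window in frames (default 14).
#' @param k comparison step between frames (default 1).
#' @param max_shift_px scene-level criterion: maximum tolerated |shift| on
#'   either axis at any frame (default 50 px).
#' @param max_blurry_fraction scene-level criterion: maximum tolerated
#'   fraction of blurry frames (default 0.05).
#' @return A `qc_params` object.
#' @export
qc_params <- function(eps_blur = 0.01, B = 14L, k = 1L, max_shift_px = 50,
                      max_blurry_fraction = 0.05) {
  if (eps_blur < 0 || eps_blur > 1) stop_config("'eps_blur' must be in [0,1]")
  if (B < 1) stop_config("'B' must be >= 1")
  if (k < 1) stop_config("'k' must be >= 1")
  structure(list(eps_blur = eps_blur, B = as.integer(B), k = as.integer(k),
                 max_shift_px = max_shift_px,
                 max_blurry_fraction = max_blurry_fraction),
            class = "qc_params")
}

#' Variance of the five-point Laplacian response
#'
#' Sharpness proxy: the response of the 3x3 five-point Laplacian (center -4,
#' cross neighbours +1) is computed in double precision on the frame
#' interior, and its variance returned. Blur suppresses high-frequency
#' content, so blurry frames have markedly lower values.
#'
#' @param frame numeric matrix.
#' @return Variance (gray-level squared units).
#' @export
laplacian_variance <- function(frame) {
  assert_matrix(frame)
  cpp_laplacian_variance(frame)
}

#' Relative difference of two Laplacian variances
#'
#' The blur statistic `|1 - v_t1 / v_t|` compared against `eps_blur`.
#'
#' @param v_t variance of the comparison (sharp) frame; must be > 0.
#' @param v_t1 variance of the tested frame.
#' @return Non-negative relative difference.
#' @export
blur_relative_difference <- function(v_t, v_t1) {
  if (v_t == 0)
    stop_degenerate("undefined variance ratio: comparison frame variance is 0")
  abs(1 - v_t1 / v_t)
}

#' Detect blurry frames and evaluate scene-level quality criteria
#'
#' Walks the stack comparing each frame's Laplacian variance against the last
#' accepted sharp frame's (step `k`). When the relative difference exceeds
#' `eps_blur` with a variance *drop*, the frame is flagged and up to `B`
#' subsequent frames are examined, each flagged until the variance returns
#' within `eps_blur` of the pre-blur level. A variance *increase* beyond the
#' threshold flags the lower-variance side of the pair (the previously
#' accepted frame) and re-anchors on the sharper frame. Flagged frames are
#' rejected from downstream quantification (but kept on disk by the callers,
#' with this report as the rejection manifest).
#'
#' Scene-level criteria: the maximum |shift| on either axis must not exceed
#' `max_shift_px`, and the blurry fraction must not exceed
#' `max_blurry_fraction`.
#'
#' @param stack a [frame_stack()].
#' @param registration_records optional data frame from [register_stack()]
#'   providing per-frame `dx`, `dy` for the shift criterion.
#' @param params a [qc_params()].
#' @return A `qc_report`: list with `frames` (per-frame data frame: variance,
#'   relative difference, blur flag, shift magnitude), `rejected` (indices),
#'   `blurry_fraction`, `max_shift`, `pass_blur`, `pass_shift`, `pass`.
#' @export
detect_blurry_frames <- function(stack, registration_records = NULL,
                                 params = qc_params()) {
  n <- stack$n_frames
  v <- vapply(seq_len(n), function(i) laplacian_variance(get_frame(stack, i)),
              numeric(1))
  flagged <- logical(n)
  reldiff <- rep(NA_real_, n)
  ref_idx <- 1L  # last accepted sharp frame
  t <- 1L + params$k
  while (t <= n) {
    d <- blur_relative_difference(v[ref_idx], v[t])
    reldiff[t] <- d
    if (d > params$eps_blur) {
      if (v[t] < v[ref_idx]) {
        # blur onset: flag and scan ahead for recovery
        flagged[t] <- TRUE
        j <- t + 1L
        while (j <= min(n, t + params$B)) {
          dj <- blur_relative_difference(v[ref_idx], v[j])
          reldiff[j] <- dj
          if (dj <= params$eps_blur) break  # sharpness is back
          flagged[j] <- TRUE
          j <- j + 1L
        }
        # resume at j: it is re-tested against the pre-blur anchor (and
        # accepted as the new anchor if sharp)
        t <- j
        next
      } else {
        # the dimmer side of the pair is the blurry one: the old anchor
        flagged[ref_idx] <- TRUE
        ref_idx <- t
      }
    } else {
      ref_idx <- t
    }
    t <- t + params$k
  }
  shift_mag <- rep(NA_real_, n)
  if (!is.null(registration_records)) {
    idx <- match(seq_len(n), registration_records$frame)
    shift_mag <- pmax(abs(registration_records$dx[idx]),
                      abs(registration_records$dy[idx]))
  }
  blurry_fraction <- sum(flagged) / n
  max_shift <- if (all(is.na(shift_mag))) NA_real_ else
    max(shift_mag, na.rm = TRUE)
  pass_blur <- blurry_fraction <= params$max_blurry_fraction
  pass_shift <- is.na(max_shift) || max_shift <= params$max_shift_px
  structure(list(
    frames = data.frame(frame = seq_len(n), variance = v,
                        rel_diff = reldiff, blurry = flagged,
                        shift_mag = shift_mag),
    rejected = which(flagged), blurry_fraction = blurry_fraction,
    max_shift = max_shift, pass_blur = pass_blur, pass_shift = pass_shift,
    pass = pass_blur && pass_shift, params = params), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "qc_report: %d/%d frames blurry (%.1f%%; limit %.1f%%) -> %s\n",
    length(x$rejected), nrow(x$frames), 100 * x$blurry_fraction,
    100 * x$params$max_blurry_fraction, if (x$pass_blur) "pass" else "FAIL"))
  if (!is.na(x$max_shift))
    cat(sprintf("  max |shift| %.2f px (limit %g px) -> %s\n", x$max_shift,
                x$params$max_shift_px, if (x$pass_shift) "pass" else "FAIL"))
  invisible(x)
}

#' Write a QC report (per-frame CSV + scene-level JSON)
#'
#' @param report a `qc_report`.
#' @param csv_path per-frame CSV path.
#' @param json_path scene-summary JSON path (includes the rejection
#'   manifest).
#' @return Invisibly, the two paths.
#' @export
write_qc_report <- function(report, csv_path, json_path) {
  write.csv(report$frames, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(rejected = report$rejected,
         blurry_fraction = report$blurry_fraction,
         max_shift = report$max_shift, pass_blur = report$pass_blur,
         pass_shift = report$pass_shift, pass = report$pass),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
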