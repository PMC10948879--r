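#' Classical per-frame cell probability backend
#'
#' A deterministic, training-free backend satisfying the probability-map
#' contract: unstained cells are detected by their internal texture (local
#' standard deviation of the lightly smoothed frame), the texture score is
#' cleaned morphologically into a foreground mask, and the mask's Euclidean
#' distance transform shapes the map so that probability is high in cell
#' interiors and falls towards cell borders -- giving the downstream
#' watershed a usable relief with valleys between touching cells.
#'
#' @param texture_sigma smoothing before the texture measure, px.
#' @param window local-statistics window side, px (odd).
#' @param score_threshold foreground cut on the robust z-score of the local
#'   texture measure (median/MAD standardized; the background, which
#'   dominates the frame, sits near 0).
#' @return A `phq_backend` object: list with `name`, `n_parameters`, and
#'   `predict(frame)` returning a probability map in `[0, 1]`.
#' @export
classical_backend <- function(texture_sigma = 1.5, window = 15L,
                              score_threshold = 10) {
  predict_fn <- function(frame) {
    assert_matrix(frame)
    # normalized convolutions: divide by the kernel mass actually inside the
    # frame so statistics stay unbiased at the frame border
    gs <- 2 * ceiling(3 * texture_sigma) + 1
    kg <- dnorm(seq(-(gs - 1) / 2, (gs - 1) / 2), sd = texture_sigma)
    kg <- kg / sum(kg)
    ones <- matrix(1, nrow(frame), ncol(frame))
    sm <- cpp_sep_convolve(frame, kg) / cpp_sep_convolve(ones, kg)
    k <- rep(1, window) / window
    mass <- cpp_sep_convolve(ones, k)
    mu <- cpp_sep_convolve(sm, k) / mass
    vv <- pmax(cpp_sep_convolve(sm * sm, k) / mass - mu^2, 0)
    s <- sqrt(vv)
    # robust standardization: the background dominates the frame, so the
    # median/MAD are background statistics whatever the frame's scaling
    md <- stats::mad(s)
    if (md <= 0) return(matrix(0, nrow(frame), ncol(frame)))
    z <- (s - median(s)) / md
    raw <- z > score_threshold
    raw <- EBImage::opening(raw, EBImage::makeBrush(5, "disc"))
    fg <- EBImage::fillHull(EBImage::closing(
      raw, EBImage::makeBrush(7, "disc")))
    # the window dilates the texture response by ~half its width; erode the
    # same amount to recover the true cell extent
    fg <- EBImage::erode(fg, EBImage::makeBrush(window, "disc"))
    fg <- as.matrix(fg) > 0
    if (!any(fg) || all(fg)) return(matrix(0, nrow(frame), ncol(frame)))
    dt <- as.matrix(EBImage::distmap(fg))
    # per-component plateau shaping: probability 1 on the inner core,
    # falling off towards the component boundary
    lab <- cpp_label_components(fg, 8L)
    prob <- matrix(0, nrow(frame), ncol(frame))
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l)
      m <- max(dt[idx])
      prob[idx] <- 0.55 + 0.45 * pmin(dt[idx] / (0.6 * m), 1)
    }
    prob
  }
  structure(list(name = "classical-texture", n_parameters = 0L,
                 predict = predict_fn), class = "phq_backend")
}

#' Evaluate a backend on one frame
#'
#' @param backend a `phq_backend`.
#' @param frame numeric matrix in `[0, 1]`.
#' @return Probability map in `[0, 1]`.
#' @export
backend_prob <- function(backend, frame) {
  if (!inherits(backend, "phq_backend")) stop_config("not a phq_backend")
  p <- backend$predict(frame)
  if (min(p) < 0 || max(p) > 1) stop_config("backend returned values outside [0,1]")
  p
}

#' Temporal-coherence fusion of probability maps (TTCM)
#'
#' The probability maps of a time window are averaged (normalized by the
#' number of time points); pixels whose coherence exceeds a high threshold
#' (default 0.9) -- i.e. pixels confidently "cell" in essentially every frame
#' of the window -- form the seed regions. Seeds are the connected components
#' of that mask, represented by their centroids.
#'
#' @param window list of probability maps (co-registered, same shape).
#' @param seed_threshold coherence cut for seeds (default 0.9).
#' @param binarize average thresholded (0/1) maps instead of raw
#'   probabilities.
#' @return List: `coherence` (matrix in `[0, 1]`), `seed_labels` (integer
#'   matrix), `seeds` (data frame label/row/col, 0-based centroids).
#' @export
ttcm <- function(window, seed_threshold = 0.9, binarize = FALSE) {
  if (!length(window)) stop_config("empty probability-map window")
  if (binarize) window <- lapply(window, function(m) (m > 0.5) * 1)
  coh <- Reduce(`+`, window) / length(window)
  seed_mask <- coh > seed_threshold
  seed_labels <- cpp_label_components(seed_mask, 8L)
  seeds <- measure_labels(seed_labels)[, c("label", "row", "col")]
  list(coherence = coh, seed_labels = seed_labels, seeds = seeds)
}

#' Marker-based watershed fusion into cell instances
#'
#' Grows one instance label per seed over the probability relief (flooding
#' from high probability downhill), restricted to the foreground mask
#' (probability above `foreground_threshold`). Seeds falling outside the
#' foreground are dropped with a warning. Foreground pixels connected to a
#' seed are all assigned; with no seeds the label map is empty.
#'
#' @param prob probability map in `[0, 1]`.
#' @param seed_labels integer matrix of seed regions (e.g. from [ttcm()]).
#' @param foreground_threshold foreground delimiter (default 0.5).
#' @return An integer instance label map; attribute `unassigned` counts
#'   foreground pixels not reached by any seed.
#' @export
watershed_instances <- function(prob, seed_labels, foreground_threshold = 0.5) {
  assert_matrix(prob)
  fg <- prob > foreground_threshold
  present <- sort(unique(seed_labels[seed_labels > 0]))
  kept <- seed_labels
  dropped <- integer(0)
  for (l in present) {
    inside <- fg[seed_labels == l]
    if (!any(inside)) {
      kept[seed_labels == l] <- 0L
      dropped <- c(dropped, l)
    }
  }
  if (length(dropped))
    warning(sprintf("dropped %d seed(s) outside the foreground", length(dropped)))
  out <- cpp_marker_watershed(prob, kept, fg)
  attr(out, "unassigned") <- sum(fg & out == 0L)
  out
}

#' Border mask of a ground-truth cell mask
#'
#' Dilate the binary mask for two iterations (3x3 box), subtract the original
#' mask (keeping only the post-dilation border), then dilate the border for
#' four further iterations. Used by the border loss.
#'
#' @param mask logical matrix.
#' @return Logical border mask.
#' @export
border_mask <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  brush <- EBImage::makeBrush(3, "box")
  d <- mask
  for (i in 1:2) d <- as.matrix(EBImage::dilate(d, brush)) > 0
  b <- d & !mask
  for (i in 1:4) b <- as.matrix(EBImage::dilate(b, brush)) > 0
  b
}

#' Background/foreground pixel-count ratio of a ground-truth mask
#'
#' The per-image class-imbalance factor weighting the background term of the
#' global loss.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return `(#background) / (#foreground)`.
#' @export
alpha_factor <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  nf <- sum(mask)
  if (nf == 0) stop_degenerate("alpha undefined: mask has no foreground")
  (length(mask) - nf) / nf
}

#' Class-imbalance-weighted global segmentation loss
#'
#' Mean over images of the per-pixel binary cross-entropy in which the
#' background term is weighted by each image's alpha factor:
#' `-(gt*log(pred) + (1-gt)*alpha*log(1-pred))`. Predictions are clipped away
#' from 0 and 1 for finiteness.
#'
#' @param pred prediction matrix in `[0, 1]`, or list of them.
#' @param gt ground-truth mask, or list.
#' @param alpha alpha factor per image (default: computed from `gt`).
#' @param clip probability clipping (default 1e-7).
#' @return Non-negative scalar.
#' @export
loss_global <- function(pred, gt, alpha = NULL, clip = 1e-7) {
  if (!is.list(pred)) { pred <- list(pred); gt <- list(gt) }
  if (is.null(alpha)) alpha <- vapply(gt, alpha_factor, numeric(1))
  alpha <- rep_len(alpha, length(pred))
  per_image <- vapply(seq_along(pred), function(i) {
    p <- pmin(pmax(pred[[i]], clip), 1 - clip)
    g <- (gt[[i]] > 0) * 1
    mean(-(g * log(p) + (1 - g) * alpha[i] * log(1 - p)))
  }, numeric(1))
  mean(per_image)
}

#' Border coverage loss
#'
#' Fraction of ground-truth border pixels covered by the (binary) prediction,
#' averaged over images: 0 when prediction and border are disjoint, 1 when
#' the prediction contains every border pixel.
#'
#' @param pred binary prediction matrix (or list).
#' @param gt_border ground-truth border mask (or list), non-empty.
#' @return Scalar in `[0, 1]`.
#' @export
loss_border <- function(pred, gt_border) {
  if (!is.list(pred)) { pred <- list(pred); gt_border <- list(gt_border) }
  per_image <- vapply(seq_along(pred), function(i) {
    b <- gt_border[[i]] > 0
    if (!any(b)) stop_degenerate("empty ground-truth border mask")
    sum((pred[[i]] > 0) & b) / sum(b)
  }, numeric(1))
  mean(per_image)
}

#' Combined segmentation training loss
#'
#' `omega * loss_global + (1 - omega) * loss_border`, with `omega` confined
#' to `[0, 0.5]` (larger values jeopardize cell separation); the default 0.4
#' balances border emphasis against global foreground/background fidelity.
#'
#' @param loss_global_value,loss_border_value component losses.
#' @param omega mixing weight in `[0, 0.5]`.
#' @return Scalar.
#' @export
total_loss <- function(loss_global_value, loss_border_value, omega = 0.4) {
  if (omega < 0 || omega > 0.5) stop_config("'omega' must lie in [0, 0.5]")
  omega * loss_global_value + (1 - omega) * loss_border_value
}

#' Mean activation heat map of a feature-map stack
#'
#' Per-pixel mean over channels, rescaled to the requested output size
#' (bilinear) and min-max normalized to `[0, 1]` for color mapping. The
#' explainability view of a backend's internal feature maps.
#'
#' @param channels list of same-shape numeric matrices.
#' @param out_size output side length(s) `c(rows, cols)` (default: input
#'   size).
#' @return Numeric matrix in `[0, 1]` (constant 0.5 for a flat stack).
#' @export
mean_activation_heatmap <- function(channels, out_size = NULL) {
  if (!length(channels)) stop_config("need at least one channel")
  m <- Reduce(`+`, channels) / length(channels)
  if (!is.null(out_size)) {
    out_size <- rep_len(as.integer(out_size), 2L)
    m <- as.matrix(EBImage::resize(m, w = out_size[1L], h = out_size[2L]))
  }
  rng <- range(m)
  if (rng[1L] == rng[2L]) return(matrix(0.5, nrow(m), ncol(m)))
  (m - rng[1L]) / (rng[2L] - rng[1L])
}

#' Instance-level cell segmentation of a scene
#'
#' For each frame `t`, the backend's probability maps over the window
#' `[t, t + window - 1]` (shrunk near the end of the stack) are fused by
#' [ttcm()] into coherence seeds, and [watershed_instances()] grows one
#' instance per seed on frame `t`'s own probability map. Per-instance
#' features (area, centroid, mean coherence, frame-border flag) are
#' extracted; instances touching the field-of-view border are flagged, not
#' deleted, so downstream metrics can exclude them.
#'
#' @param stack normalized cell-channel [frame_stack()] (values `[0, 1]`).
#' @param backend a `phq_backend` (default [classical_backend()]).
#' @param accepted_frames frames to segment (default: all).
#' @param window TTCM window length in frames (default 5).
#' @param seed_threshold,foreground_threshold see [ttcm()] and
#'   [watershed_instances()].
#' @return List: `labels` (per accepted frame instance maps) and `features`
#'   (data frame: frame, label, area_px, area_um2, row, col, coherence,
#'   border_flag).
#' @export
segment_scene <- function(stack, backend = classical_backend(),
                          accepted_frames = NULL, window = 5L,
                          seed_threshold = 0.9, foreground_threshold = 0.5) {
  if (is.null(accepted_frames)) accepted_frames <- seq_len(stack$n_frames)
  if (window < 1) stop_config("'window' must be >= 1")
  n <- length(accepted_frames)
  probs <- vector("list", n)
  get_prob <- function(i) {
    if (is.null(probs[[i]]))
      probs[[i]] <<- backend_prob(backend, get_frame(stack, accepted_frames[i]))
    probs[[i]]
  }
  labels <- vector("list", n)
  feats <- list()
  for (i in seq_len(n)) {
    idx <- i:min(n, i + window - 1L)
    fused <- ttcm(lapply(idx, get_prob), seed_threshold = seed_threshold)
    lab <- suppressWarnings(
      watershed_instances(get_prob(i), fused$seed_labels,
                          foreground_threshold))
    labels[[i]] <- lab
    tab <- measure_labels(lab, stack$pixel_size)
    if (nrow(tab)) {
      tab$coherence <- vapply(tab$label, function(l)
        mean(fused$coherence[lab == l]), numeric(1))
      tab$border_flag <- vapply(tab$label, function(l) {
        px <- which(lab == l)
        r <- (px - 1L) %% nrow(lab)
        c <- (px - 1L) %/% nrow(lab)
        any(r == 0L | c == 0L | r == nrow(lab) - 1L | c == ncol(lab) - 1L)
      }, logical(1))
      tab$frame <- rep(accepted_frames[i], nrow(tab))
      feats[[length(feats) + 1L]] <- tab
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(label = integer(0), area_px = integer(0),
               area_um2 = numeric(0), row = numeric(0), col = numeric(0),
               coherence = numeric(0), border_flag = logical(0),
               frame = integer(0))
  list(labels = labels, features = features)
}

#' Mean instance-level intersection-over-union against ground truth
#'
#' Per frame: each ground-truth instance is matched to the predicted
#' instance of maximal IoU; the sum of matched IoUs divided by the
#' ground-truth instance count. Averaged over frames.
#'
#' @param pred_labels list of predicted instance maps.
#' @param gt_labels list of ground-truth instance maps.
#' @param exclude_border ignore ground-truth instances touching the frame
#'   border.
#' @return Mean IoU in `[0, 1]`.
#' @export
mean_iou <- function(pred_labels, gt_labels, exclude_border = FALSE) {
  per_frame <- vapply(seq_along(pred_labels), function(i) {
    gt <- gt_labels[[i]]
    pr <- pred_labels[[i]]
    ids <- setdiff(unique(as.vector(gt)), 0L)
    if (!length(ids)) return(NA_real_)
    ious <- vapply(ids, function(g) {
      gpx <- gt == g
      cand <- setdiff(unique(pr[gpx]), 0L)
      if (!length(cand)) return(0)
      max(vapply(cand, function(p) {
        ppx <- pr == p
        sum(gpx & ppx) / sum(gpx | ppx)
      }, numeric(1)))
    }, numeric(1))
    mean(ious)
  }, numeric(1))
  mean(per_frame, na.rm = TRUE)
}
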