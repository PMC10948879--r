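#' Segment fluorescent aggregates by fixed thresholding
#'
#' On a globally normalized frame (values in `[0, 1]`) the aggregates are the
#' pixels strictly above the threshold (default 0.5); a value exactly at the
#' threshold is background.
#'
#' @param frame numeric matrix in `[0, 1]`.
#' @param threshold foreground threshold (default 0.5).
#' @return Logical mask.
#' @export
segment_aggregates <- function(frame, threshold = 0.5) {
  assert_matrix(frame)
  frame > threshold
}

#' Label a binary mask and measure per-object features
#'
#' Connected-component labeling (8-connectivity by default) followed by
#' per-component area (pixel count, and um^2 via the pixel size) and centroid
#' (mean pixel coordinate, 0-based `(row, col)`).
#'
#' @param mask logical matrix.
#' @param pixel_size micrometers per pixel.
#' @param connectivity 8 (default) or 4.
#' @return Data frame: `label`, `area_px`, `area_um2`, `row`, `col`.
#' @export
label_and_measure <- function(mask, pixel_size = 0.103, connectivity = 8L) {
  if (!is.logical(mask)) mask <- mask > 0
  lab <- cpp_label_components(mask, as.integer(connectivity))
  measure_labels(lab, pixel_size)
}

measure_labels <- function(lab, pixel_size = 0.103) {
  idx <- which(lab > 0)
  if (!length(idx))
    return(data.frame(label = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), row = numeric(0),
                      col = numeric(0)))
  l <- lab[idx]
  r <- (idx - 1L) %% nrow(lab)      # 0-based row
  c <- (idx - 1L) %/% nrow(lab)     # 0-based col
  area <- tabulate(l)
  labels <- which(area > 0)
  data.frame(label = labels, area_px = area[labels],
             area_um2 = area[labels] * pixel_size^2,
             row = as.vector(tapply(r, l, mean)),
             col = as.vector(tapply(c, l, mean)))
}

#' Centroid-displacement threshold in pixels
#'
#' The physical displacement criterion converted to pixels:
#' `round(threshold_um / pixel_size)`; 0.7 um at 0.103 um/px gives 7 px.
#'
#' @param threshold_um displacement threshold, micrometers.
#' @param pixel_size micrometers per pixel.
#' @return Integer pixel threshold.
#' @export
displacement_threshold_px <- function(threshold_um = 0.7,
                                      pixel_size = 0.103) {
  if (pixel_size <= 0) stop_config("'pixel_size' must be > 0")
  if (threshold_um <= 0) stop_config("'threshold_um' must be > 0")
  as.integer(round(threshold_um / pixel_size))
}

#' Match aggregate labels between two consecutive frames
#'
#' One-to-one greedy nearest-centroid matching: pairs are assigned in order
#' of increasing centroid distance, each label used at most once, within a
#' maximum radius. Unmatched previous labels map to `NA` ("gone").
#'
#' @param prev,cur data frames from [label_and_measure()].
#' @param max_radius maximum matching distance, px.
#' @return Data frame: `prev_label`, `cur_label` (NA when gone), `distance`.
#' @export
match_labels <- function(prev, cur, max_radius = 15) {
  if (!nrow(prev))
    return(data.frame(prev_label = integer(0), cur_label = integer(0),
                      distance = numeric(0)))
  if (!nrow(cur))
    return(data.frame(prev_label = prev$label, cur_label = NA_integer_,
                      distance = NA_real_))
  d <- sqrt(outer(prev$row, cur$row, "-")^2 + outer(prev$col, cur$col, "-")^2)
  assign_cur <- rep(NA_integer_, nrow(prev))
  dist_out <- rep(NA_real_, nrow(prev))
  repeat {
    m <- which.min(d)
    if (!length(m) || !is.finite(d[m]) || d[m] > max_radius) break
    i <- (m - 1L) %% nrow(d) + 1L
    j <- (m - 1L) %/% nrow(d) + 1L
    assign_cur[i] <- cur$label[j]
    dist_out[i] <- d[m]
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  data.frame(prev_label = prev$label, cur_label = assign_cur,
             distance = dist_out)
}

#' Detect phagocytosis events between two consecutive frames
#'
#' An aggregate is scored as phagocytosed when its area drops to at most
#' `area_ratio` of the previous frame's area, or its matched centroid moves
#' by at least `disp_px` pixels (the two criteria are combined with
#' `rule = "or"` by default; `"and"` requires both), or it vanishes while its
#' previous area was already below `vanish_area_px` (a small aggregate
#' swallowed whole between frames).
#'
#' @param prev,cur data frames from [label_and_measure()].
#' @param mapping data frame from [match_labels()].
#' @param area_ratio area-halving criterion (default 0.5).
#' @param disp_px displacement criterion in px (default 7, i.e. 0.7 um at
#'   0.103 um/px).
#' @param rule `"or"` (default) or `"and"`.
#' @param vanish_area_px smallness threshold for the vanish criterion.
#' @return Data frame of events: `prev_label`, `cur_label`, `area_before`,
#'   `area_after`, `displacement`, `criterion`.
#' @export
detect_phagocytosis <- function(prev, cur, mapping, area_ratio = 0.5,
                                disp_px = 7, rule = c("or", "and"),
                                vanish_area_px = 25) {
  rule <- match.arg(rule)
  out <- list()
  for (i in seq_len(nrow(mapping))) {
    pl <- mapping$prev_label[i]
    cl <- mapping$cur_label[i]
    a0 <- prev$area_px[prev$label == pl]
    if (is.na(cl)) {
      if (a0 <= vanish_area_px)
        out[[length(out) + 1L]] <- data.frame(
          prev_label = pl, cur_label = NA_integer_, area_before = a0,
          area_after = 0, displacement = NA_real_, criterion = "vanished")
      next
    }
    a1 <- cur$area_px[cur$label == cl]
    disp <- mapping$distance[i]
    hit_area <- a1 <= area_ratio * a0
    hit_disp <- disp >= disp_px
    hit <- if (rule == "or") hit_area || hit_disp else hit_area && hit_disp
    if (hit)
      out[[length(out) + 1L]] <- data.frame(
        prev_label = pl, cur_label = cl, area_before = a0, area_after = a1,
        displacement = disp,
        criterion = if (hit_area && hit_disp) "area+movement"
                    else if (hit_area) "area" else "movement")
  }
  if (!length(out))
    return(data.frame(prev_label = integer(0), cur_label = integer(0),
                      area_before = numeric(0), area_after = numeric(0),
                      displacement = numeric(0), criterion = character(0)))
  do.call(rbind, out)
}

#' Segment, track and quantify aggregates over a scene
#'
#' Runs the full aggregate branch on the accepted frames of a registered,
#' normalized stack: fixed-threshold segmentation, 8-connected labeling and
#' measurement, frame-to-frame nearest-centroid matching into persistent
#' aggregate tracks, event detection by the area-halving / centroid-movement
#' rule (each track fires at most once), and per-frame time series. "Area
#' eaten" credits the track's initial area once, at the event frame, keeping
#' the cumulative curve monotone.
#'
#' @param stack a normalized, registered [frame_stack()] (values `[0, 1]`).
#' @param accepted_frames frame indices to quantify (default: all).
#' @param threshold segmentation threshold.
#' @param area_ratio,disp_px,rule,vanish_area_px see [detect_phagocytosis()].
#' @param match_radius see [match_labels()].
#' @param pixel_size micrometers per pixel (default: the stack's).
#' @return List: `tables` (per-frame measurements with `frame` and persistent
#'   `track` columns), `events` (track, frame, criterion, area credited),
#'   `series` (per accepted frame: total area, count, cumulative area eaten,
#'   in px and um^2).
#' @export
quantify_aggregates <- function(stack, accepted_frames = NULL,
                                threshold = 0.5, area_ratio = 0.5,
                                disp_px = NULL, rule = "or",
                                vanish_area_px = 25, match_radius = 15,
                                pixel_size = NULL) {
  if (is.null(accepted_frames)) accepted_frames <- seq_len(stack$n_frames)
  if (is.null(pixel_size)) pixel_size <- stack$pixel_size
  if (is.null(disp_px))
    disp_px <- displacement_threshold_px(pixel_size = pixel_size)

  tabs <- list()
  events <- list()
  track_of <- integer(0)     # current-frame label -> track id
  track_area0 <- numeric(0)  # track id -> area at first appearance
  fired <- logical(0)
  next_track <- 0L
  prev_tab <- NULL
  prev_track_of <- NULL
  for (t in accepted_frames) {
    mask <- segment_aggregates(get_frame(stack, t), threshold)
    tab <- label_and_measure(mask, pixel_size)
    if (is.null(prev_tab)) {
      track_of <- seq_len(nrow(tab))
      next_track <- nrow(tab)
      track_area0 <- tab$area_px
      fired <- rep(FALSE, nrow(tab))
    } else {
      mapping <- match_labels(prev_tab, tab, max_radius = match_radius)
      ev <- detect_phagocytosis(prev_tab, tab, mapping,
                                area_ratio = area_ratio, disp_px = disp_px,
                                rule = rule, vanish_area_px = vanish_area_px)
      track_of_new <- rep(NA_integer_, nrow(tab))
      for (i in seq_len(nrow(mapping))) {
        cl <- mapping$cur_label[i]
        if (!is.na(cl))
          track_of_new[tab$label == cl] <-
            prev_track_of[prev_tab$label == mapping$prev_label[i]]
      }
      for (j in which(is.na(track_of_new))) {  # new appearances
        next_track <- next_track + 1L
        track_of_new[j] <- next_track
        track_area0[next_track] <- tab$area_px[j]
        fired[next_track] <- FALSE
      }
      track_of <- track_of_new
      for (i in seq_len(nrow(ev))) {
        tr <- prev_track_of[prev_tab$label == ev$prev_label[i]]
        if (fired[tr]) next
        fired[tr] <- TRUE
        events[[length(events) + 1L]] <- data.frame(
          track = tr, frame = t, criterion = ev$criterion[i],
          area_before = ev$area_before[i], area_after = ev$area_after[i],
          displacement = ev$displacement[i],
          area_credited_px = track_area0[tr])
      }
    }
    if (nrow(tab)) tab$track <- track_of
    else tab$track <- integer(0)
    tab$frame <- rep(t, nrow(tab))
    tabs[[length(tabs) + 1L]] <- tab
    prev_tab <- tab
    prev_track_of <- track_of
  }
  tables <- do.call(rbind, tabs)
  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(track = integer(0), frame = integer(0),
               criterion = character(0), area_before = numeric(0),
               area_after = numeric(0), displacement = numeric(0),
               area_credited_px = numeric(0))
  list(tables = tables, events = events_df,
       series = aggregate_time_series(tables, events_df, accepted_frames,
                                      pixel_size))
}

#' Per-frame aggregate time series
#'
#' Totals per accepted frame (area, count) and the cumulative "area eaten"
#' curve, which is non-decreasing: each event credits its track's initial
#' area once at the event frame.
#'
#' @param tables per-frame measurement tables with `frame` column.
#' @param events event data frame with `frame` and `area_credited_px`.
#' @param accepted_frames ordered frame indices of the series.
#' @param pixel_size micrometers per pixel.
#' @return Data frame: `frame`, `total_area_px`, `count`, `eaten_px`,
#'   `eaten_um2`.
#' @export
aggregate_time_series <- function(tables, events, accepted_frames,
                                  pixel_size = 0.103) {
  per_frame <- lapply(accepted_frames, function(t) {
    sub <- tables[tables$frame == t, , drop = FALSE]
    data.frame(frame = t, total_area_px = sum(sub$area_px),
               count = nrow(sub))
  })
  out <- do.call(rbind, per_frame)
  eaten <- numeric(nrow(out))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      at <- which(out$frame >= events$frame[i])
      eaten[at] <- eaten[at] + events$area_credited_px[i]
    }
  }
  out$eaten_px <- eaten
  out$eaten_um2 <- eaten * pixel_size^2
  out
}
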