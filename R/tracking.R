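#' Shift-correct per-frame detections into reference coordinates
#'
#' Subtracts each frame's estimated translation from its detections'
#' centroids so all coordinates live in the reference (frame-1) system;
#' detections on QC-rejected frames are dropped.
#'
#' @param detections data frame with `frame`, `row`, `col` (0-based px).
#' @param records registration records with `frame`, `dx`, `dy`.
#' @param rejected_frames frame indices to exclude.
#' @return `detections` with corrected coordinates.
#' @export
correct_centroids <- function(detections, records, rejected_frames = integer(0)) {
  idx <- match(detections$frame, records$frame)
  if (anyNA(idx)) stop_config("missing transform for some frames")
  out <- detections
  out$row <- detections$row - records$dy[idx]
  out$col <- detections$col - records$dx[idx]
  out[!out$frame %in% rejected_frames, , drop = FALSE]
}

#' Link per-frame detections into tracks
#'
#' Deterministic greedy frame-to-frame nearest-neighbour assignment: between
#' consecutive observed frames, pairs are linked in order of increasing
#' centroid distance (ties broken by smaller label) within `max_jump`;
#' unmatched detections start new tracks; a missed detection ends its track
#' (no gap closing).
#'
#' @param detections data frame with `frame`, `label`, `row`, `col`,
#'   `area_px` (reference coordinates; see [correct_centroids()]).
#' @param max_jump maximum link distance, px.
#' @return List of tracks: each a data frame of ordered
#'   `(frame, row, col, area_px)` plus a `track` id column.
#' @export
link_tracks <- function(detections, max_jump = 30) {
  frames <- sort(unique(detections$frame))
  tracks <- list()        # track id -> data frame rows
  open_of <- integer(0)   # current-frame detection row name -> track id
  prev <- NULL
  for (t in frames) {
    cur <- detections[detections$frame == t, , drop = FALSE]
    cur <- cur[order(cur$label), , drop = FALSE]
    assigned <- rep(NA_integer_, nrow(cur))
    if (!is.null(prev) && nrow(prev) && nrow(cur)) {
      d <- sqrt(outer(prev$row, cur$row, "-")^2 +
                  outer(prev$col, cur$col, "-")^2)
      repeat {
        m <- which.min(d)
        if (!length(m) || !is.finite(d[m]) || d[m] > max_jump) break
        i <- (m - 1L) %% nrow(d) + 1L
        j <- (m - 1L) %/% nrow(d) + 1L
        assigned[j] <- open_of[i]
        d[i, ] <- Inf
        d[, j] <- Inf
      }
    }
    for (j in seq_len(nrow(cur))) {
      if (is.na(assigned[j])) {
        assigned[j] <- length(tracks) + 1L
        tracks[[assigned[j]]] <- list()
      }
      tracks[[assigned[j]]][[length(tracks[[assigned[j]]]) + 1L]] <-
        data.frame(frame = cur$frame[j], row = cur$row[j], col = cur$col[j],
                   area_px = cur$area_px[j])
    }
    open_of <- assigned
    prev <- cur
  }
  lapply(seq_along(tracks), function(i) {
    df <- do.call(rbind, tracks[[i]])
    df$track <- i
    df
  })
}

#' Keep tracks of sufficient duration
#'
#' Duration is `(n_points - 1) * frame_interval` minutes; tracks lasting at
#' least `min_duration` (inclusive) are retained.
#'
#' @param tracks list of track data frames (from [link_tracks()]).
#' @param frame_interval minutes per frame.
#' @param min_duration minimum duration, minutes (default 100).
#' @return Filtered list of tracks.
#' @export
filter_tracks <- function(tracks, frame_interval = 2, min_duration = 100) {
  keep <- vapply(tracks, function(tr)
    (nrow(tr) - 1L) * frame_interval >= min_duration, logical(1))
  tracks[keep]
}

#' Motility statistics of one track
#'
#' Per-step speed is the Euclidean step length divided by the frame
#' interval; the track's mean speed is the mean of step speeds, and total
#' displacement the sum of step lengths (always at least the net
#' start-to-end distance).
#'
#' @param track a track data frame with at least 2 points.
#' @param frame_interval minutes per frame.
#' @param pixel_size micrometers per pixel (for the um-scaled outputs).
#' @return Data frame row: `track`, `n_points`, `duration_min`,
#'   `mean_speed_px_min`, `mean_speed_um_min`, `total_displacement_px`,
#'   `total_displacement_um`, `net_displacement_px`.
#' @export
motility <- function(track, frame_interval = 2, pixel_size = 0.103) {
  if (nrow(track) < 2)
    stop_degenerate("motility undefined for tracks with < 2 points")
  steps <- sqrt(diff(track$row)^2 + diff(track$col)^2)
  dt <- diff(track$frame) * frame_interval
  speeds <- steps / dt
  data.frame(
    track = track$track[1L], n_points = nrow(track),
    duration_min = (nrow(track) - 1L) * frame_interval,
    mean_speed_px_min = mean(speeds),
    mean_speed_um_min = mean(speeds) * pixel_size,
    total_displacement_px = sum(steps),
    total_displacement_um = sum(steps) * pixel_size,
    net_displacement_px = sqrt((track$row[nrow(track)] - track$row[1L])^2 +
                                 (track$col[nrow(track)] - track$col[1L])^2))
}

#' Track cells and summarize motility for a scene
#'
#' Shift-corrects the detections, links them into tracks, applies the
#' minimum-duration filter, and computes per-track motility.
#'
#' @param detections per-frame cell features (`frame`, `label`, `row`,
#'   `col`, `area_px`).
#' @param records registration records.
#' @param rejected_frames QC-rejected frame indices.
#' @param frame_interval minutes per frame.
#' @param pixel_size micrometers per pixel.
#' @param max_jump link radius, px.
#' @param min_duration track filter, minutes.
#' @return List: `tracks` (filtered) and `stats` (per-track motility data
#'   frame).
#' @export
track_scene <- function(detections, records, rejected_frames = integer(0),
                        frame_interval = 2, pixel_size = 0.103,
                        max_jump = 30, min_duration = 100) {
  det <- correct_centroids(detections, records, rejected_frames)
  tracks <- filter_tracks(link_tracks(det, max_jump = max_jump),
                          frame_interval = frame_interval,
                          min_duration = min_duration)
  stats <- if (length(tracks))
    do.call(rbind, lapply(tracks, motility,
                          frame_interval = frame_interval,
                          pixel_size = pixel_size))
  else data.frame(track = integer(0), n_points = integer(0),
                  duration_min = numeric(0), mean_speed_px_min = numeric(0),
                  mean_speed_um_min = numeric(0),
                  total_displacement_px = numeric(0),
                  total_displacement_um = numeric(0),
                  net_displacement_px = numeric(0))
  list(tracks = tracks, stats = stats)
}
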