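#' Per-frame scene time series with headline ratios
#'
#' Joins the aggregate series with per-frame cell summaries on the accepted
#' frames and derives the two phagocytosis ratios: area eaten per cell
#' (eaten / cell count) and area eaten per cell surface unit (eaten / total
#' cell area). Frames with a zero denominator get `NA` (guarded, not
#' imputed as 0).
#'
#' @param aggregate_series data frame from [aggregate_time_series()].
#' @param cell_features per-frame cell feature table from [segment_scene()].
#' @param motility_stats optional per-track motility (scene-level scalars
#'   are attached as attributes).
#' @param frame_interval minutes per frame (for the time axis).
#' @return Data frame: frame, time_min, eaten_px/um2, cell_count,
#'   mean_cell_area_px, total_cell_area_px, eaten_per_cell,
#'   eaten_per_cell_area.
#' @export
scene_series <- function(aggregate_series, cell_features,
                         motility_stats = NULL, frame_interval = 2) {
  cells <- do.call(rbind, lapply(split(cell_features, cell_features$frame),
    function(sub) data.frame(frame = sub$frame[1L], cell_count = nrow(sub),
                             mean_cell_area_px = mean(sub$area_px),
                             total_cell_area_px = sum(sub$area_px))))
  out <- merge(aggregate_series, cells, by = "frame", all = FALSE)
  if (!nrow(out)) stop_config("no common frames between aggregate and cell series")
  out <- out[order(out$frame), , drop = FALSE]
  out$time_min <- (out$frame - 1L) * frame_interval
  out$eaten_per_cell <- ifelse(out$cell_count > 0,
                               out$eaten_px / out$cell_count, NA_real_)
  out$eaten_per_cell_area <- ifelse(out$total_cell_area_px > 0,
                                    out$eaten_px / out$total_cell_area_px,
                                    NA_real_)
  if (!is.null(motility_stats) && nrow(motility_stats)) {
    attr(out, "mean_speed_um_min") <- mean(motility_stats$mean_speed_um_min)
    attr(out, "total_displacement_um") <-
      mean(motility_stats$total_displacement_um)
  }
  rownames(out) <- NULL
  out
}

#' Mean of a series over an early time window
#'
#' Arithmetic mean of the metric over frames whose timestamps fall inside
#' `[t_start, t_end]` minutes (default the 0-200 min window used for
#' condition-level summaries). `NA` values (guarded ratios) are excluded.
#'
#' @param series data frame with a `time_min` column.
#' @param metric column name to average.
#' @param t_start,t_end window bounds, minutes.
#' @return Scalar mean.
#' @export
window_mean <- function(series, metric, t_start = 0, t_end = 200) {
  if (!metric %in% names(series)) stop_config(sprintf("no column '%s'", metric))
  sel <- series$time_min >= t_start & series$time_min <= t_end
  if (!any(sel)) stop_config("series does not cover the requested window")
  v <- series[[metric]][sel]
  v <- v[!is.na(v)]
  if (!length(v)) stop_config("window contains only missing values")
  mean(v)
}

#' Two-condition comparison with significance annotation
#'
#' Two-sided Mann-Whitney-Wilcoxon rank-sum test between per-acquisition
#' samples of two conditions, annotated `ns` (p >= 0.05), `*` (p < 0.05),
#' `**` (p < 0.01), `***` (p < 0.001).
#'
#' @param samples_a,samples_b numeric vectors (one value per acquisition).
#' @return List: `statistic` (W), `p_value`, `annotation`.
#' @export
compare_conditions <- function(samples_a, samples_b) {
  if (!length(samples_a) || !length(samples_b))
    stop_config("both conditions need at least one sample")
  ht <- suppressWarnings(wilcox.test(samples_a, samples_b,
                                     alternative = "two.sided"))
  p <- ht$p.value
  if (is.na(p)) p <- 1  # degenerate case: all values tied across groups
  list(statistic = unname(ht$statistic), p_value = p,
       annotation = p_annotation(p))
}

#' Significance annotation for a p-value
#'
#' @param p p-value.
#' @return `"ns"`, `"*"`, `"**"` or `"***"`.
#' @export
p_annotation <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Run the full quantification pipeline
#'
#' Orchestrates, per scene: normalization of both channels, cascade
#' registration on the aggregate channel, blur/shift quality control,
#' aggregate quantification with phagocytosis detection, temporal-coherence
#' cell instance segmentation, shift-corrected tracking, and the per-scene
#' time series. Then, per condition: the mean curve over scenes and the
#' 0-200 min window means (one scalar per acquisition and metric); with
#' exactly two conditions, Mann-Whitney-Wilcoxon comparisons. Every
#' intermediate artifact is persisted as CSV/JSON under `out_dir`; per-scene
#' failures are isolated and reported while the run continues.
#'
#' @param config list (or path to a YAML file) with `conditions`: a list of
#'   `list(name =, scenes = list(<scene_config arguments> ...))`; optional
#'   `params` overriding defaults (`window`, `seed_threshold`,
#'   `foreground_threshold`, `threshold`, `eps_blur`, `B`, `max_shift_px`,
#'   `max_blurry_fraction`, `min_duration`, `max_jump`, `t_start`, `t_end`).
#' @param out_dir output directory.
#' @param make_figures write time-course PNG panels (default TRUE).
#' @return Invisible list: per-scene series, per-condition window means,
#'   comparison results (when two conditions).
#' @export
run_pipeline <- function(config, out_dir, make_figures = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prm <- modifyList(list(window = 5L, seed_threshold = 0.9,
                         foreground_threshold = 0.5, threshold = 0.5,
                         eps_blur = 0.01, B = 14L, max_shift_px = 50,
                         max_blurry_fraction = 0.05, min_duration = 100,
                         max_jump = 30, t_start = 0, t_end = 200),
                    config$params %||% list())
  all_series <- list()
  failures <- list()
  for (cond in config$conditions) {
    cdir <- file.path(out_dir, cond$name)
    dir.create(cdir, showWarnings = FALSE)
    for (si in seq_along(cond$scenes)) {
      sdir <- file.path(cdir, sprintf("scene%02d", si))
      res <- tryCatch(
        run_scene(cond$scenes[[si]], sdir, prm),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(condition = cond$name, scene = si,
               message = conditionMessage(res))
        next
      }
      all_series[[length(all_series) + 1L]] <-
        list(condition = cond$name, scene = si, series = res$series)
    }
  }
  if (length(failures))
    jsonlite::write_json(failures, file.path(out_dir, "failures.json"),
                         auto_unbox = TRUE)

  metrics <- c("eaten_per_cell", "eaten_per_cell_area", "cell_count",
               "mean_cell_area_px")
  conds <- unique(vapply(all_series, `[[`, "", "condition"))
  summaries <- lapply(conds, function(cn) {
    sers <- Filter(function(s) s$condition == cn, all_series)
    vals <- sapply(metrics, function(m) {
      per_scene <- vapply(sers, function(s)
        window_mean(s$series, m, prm$t_start, prm$t_end), numeric(1))
      mean(per_scene)
    })
    per_scene_tab <- do.call(rbind, lapply(sers, function(s) {
      row <- as.data.frame(as.list(vapply(metrics, function(m)
        window_mean(s$series, m, prm$t_start, prm$t_end), numeric(1))))
      row$scene <- s$scene
      row
    }))
    list(condition = cn, acquisition_mean = as.list(vals),
         per_scene = per_scene_tab)
  })
  names(summaries) <- conds
  summary_tab <- do.call(rbind, lapply(summaries, function(s) {
    df <- as.data.frame(s$acquisition_mean)
    df$condition <- s$condition
    df
  }))
  write.csv(summary_tab, file.path(out_dir, "condition_summary.csv"),
            row.names = FALSE)

  comparison <- NULL
  if (length(conds) == 2L) {
    comparison <- lapply(metrics, function(m) {
      a <- summaries[[conds[1L]]]$per_scene[[m]]
      b <- summaries[[conds[2L]]]$per_scene[[m]]
      cc <- compare_conditions(a, b)
      data.frame(metric = m, statistic = cc$statistic,
                 p_value = cc$p_value, annotation = cc$annotation)
    })
    comparison <- do.call(rbind, comparison)
    write.csv(comparison, file.path(out_dir, "comparison.csv"),
              row.names = FALSE)
  }
  if (make_figures && length(all_series))
    plot_time_courses(all_series, metrics,
                      file.path(out_dir, "time_courses.png"))
  invisible(list(series = all_series, summaries = summaries,
                 comparison = comparison, failures = failures))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One scene end to end; persists per-stage artifacts under `sdir`.
run_scene <- function(scene_args, sdir, prm) {
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  scene <- generate_scene(do.call(scene_config, scene_args))
  agg_n <- normalize_stack(scene$aggregates, "aggregate")
  cell_n <- normalize_stack(scene$cells, "cell")
  reg <- register_stack(agg_n$stack)
  write_registration(reg$records, file.path(sdir, "registration.csv"))
  # blur is an optical, whole-field fault: both channels blur together. The
  # statistic is evaluated on the cell channel, whose content is conserved
  # under motion, so it stays specific to focus loss rather than to genuine
  # aggregate-content change (phagocytosis).
  qc <- detect_blurry_frames(
    scene$cells, reg$records,
    qc_params(eps_blur = prm$eps_blur, B = prm$B,
              max_shift_px = prm$max_shift_px,
              max_blurry_fraction = prm$max_blurry_fraction))
  write_qc_report(qc, file.path(sdir, "qc_frames.csv"),
                  file.path(sdir, "qc_summary.json"))
  accepted <- setdiff(seq_len(scene$aggregates$n_frames), qc$rejected)
  agg <- quantify_aggregates(reg$aligned, accepted,
                             threshold = prm$threshold)
  write.csv(agg$tables, file.path(sdir, "aggregates.csv"),
            row.names = FALSE)
  write.csv(agg$events, file.path(sdir, "phagocytosis_events.csv"),
            row.names = FALSE)
  # cells are segmented in their native frame, then centroids are
  # shift-corrected during tracking; instance features are reported per frame
  seg <- segment_scene(cell_n$stack, accepted_frames = accepted,
                       window = prm$window,
                       seed_threshold = prm$seed_threshold,
                       foreground_threshold = prm$foreground_threshold)
  write.csv(seg$features, file.path(sdir, "cells.csv"), row.names = FALSE)
  trk <- track_scene(seg$features, reg$records, qc$rejected,
                     frame_interval = scene$cells$frame_interval,
                     pixel_size = scene$cells$pixel_size,
                     max_jump = prm$max_jump,
                     min_duration = prm$min_duration)
  write.csv(trk$stats, file.path(sdir, "motility.csv"), row.names = FALSE)
  series <- scene_series(agg$series, seg$features, trk$stats,
                         frame_interval = scene$cells$frame_interval)
  write.csv(series, file.path(sdir, "series.csv"), row.names = FALSE)
  list(series = series, qc = qc, tracking = trk)
}

plot_time_courses <- function(all_series, metrics, path) {
  df <- do.call(rbind, lapply(all_series, function(s) {
    long <- do.call(rbind, lapply(metrics, function(m)
      data.frame(time_min = s$series$time_min, value = s$series[[m]],
                 metric = m)))
    long$condition <- s$condition
    long$scene <- s$scene
    long
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = time_min, y = value, colour = condition,
    group = interaction(condition, scene))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
  grDevices::png(path, width = 1400, height = 900, res = 150)
  print(p)
  grDevices::dev.off()
  invisible(path)
}

utils::globalVariables(c("time_min", "value", "condition", "scene"))
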