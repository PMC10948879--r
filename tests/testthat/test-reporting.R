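test_that("scene series joins channels and guards zero denominators", {
  agg <- data.frame(frame = 1:3, total_area_px = c(100, 90, 80),
                    count = c(5, 5, 4), eaten_px = c(0, 100, 100),
                    eaten_um2 = c(0, 1.06, 1.06))
  cells <- data.frame(frame = rep(1:3, each = 2), label = rep(1:2, 3),
                      area_px = 200, area_um2 = 2, row = 0, col = 0,
                      coherence = 1, border_flag = FALSE)
  ser <- scene_series(agg, cells)
  expect_equal(ser$eaten_per_cell, c(0, 50, 50))
  expect_equal(ser$eaten_per_cell_area, c(0, 100 / 400, 100 / 400))
  expect_equal(ser$time_min, c(0, 2, 4))
  # ten cells sharing 100 px eaten -> 10 px per cell
  cells10 <- do.call(rbind, lapply(1:10, function(l)
    transform(cells[cells$label == 1 & cells$frame == 2, ], label = l)))
  ser2 <- scene_series(agg[2, , drop = FALSE], cells10)
  expect_equal(ser2$eaten_per_cell, 10)
})

test_that("window means average the 0-200 minute segment", {
  const <- data.frame(time_min = seq(0, 300, by = 2), v = 7)
  expect_equal(window_mean(const, "v"), 7)
  ramp <- data.frame(time_min = seq(0, 200, by = 2),
                     v = seq(0, 200, by = 2))
  expect_equal(window_mean(ramp, "v"), 100)
  late <- data.frame(time_min = seq(300, 400, by = 2), v = 1)
  expect_error(window_mean(late, "v"), class = "phagoquant_config_error")
  withna <- data.frame(time_min = c(0, 2, 4), v = c(1, NA, 3))
  expect_equal(window_mean(withna, "v"), 2)
})

test_that("condition comparison reproduces the exact rank-sum null", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(101, 102, 103, 104, 105)
  res <- compare_conditions(a, b)
  # enumeration oracle: all C(10,5) assignments of ranks; the observed
  # separation is the most extreme on both sides
  combos <- combn(10, 5)
  w <- colSums(matrix(seq_len(10)[combos], nrow = 5)) - 5 * 6 / 2
  p_exact <- mean(w <= min(w)) + mean(w >= max(w))
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  expect_equal(res$annotation, "**")  # 0.0079 < 0.01
  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$annotation, "ns")
  expect_error(compare_conditions(numeric(0), b),
               class = "phagoquant_config_error")
})

test_that("annotation tiers follow the printed cutpoints exactly", {
  expect_equal(p_annotation(0.5), "ns")
  expect_equal(p_annotation(0.05), "ns")
  expect_equal(p_annotation(0.049), "*")
  expect_equal(p_annotation(0.01), "*")
  expect_equal(p_annotation(0.009), "**")
  expect_equal(p_annotation(0.001), "**")
  expect_equal(p_annotation(0.0009), "***")
})

pipeline_config <- function() list(
  conditions = list(
    list(name = "WT", scenes = list(
      list(frame_size = 192L, n_frames = 12L, n_cells = 3L,
           n_aggregates = 8L,
           phagocytosis_events = list(list(1, 5, "shrink")),
           rng_seed = 301L),
      list(frame_size = 192L, n_frames = 12L, n_cells = 3L,
           n_aggregates = 8L,
           phagocytosis_events = list(list(1, 6, "shrink")),
           rng_seed = 302L))),
    list(name = "FTD", scenes = list(
      list(frame_size = 192L, n_frames = 12L, n_cells = 3L,
           n_aggregates = 8L,
           phagocytosis_events = list(list(1, 4, "shrink"),
                                      list(2, 5, "shrink"),
                                      list(3, 6, "shrink")),
           rng_seed = 401L),
      list(frame_size = 192L, n_frames = 12L, n_cells = 3L,
           n_aggregates = 8L,
           phagocytosis_events = list(list(1, 4, "shrink"),
                                      list(2, 6, "shrink"),
                                      list(3, 7, "shrink")),
           rng_seed = 402L)))),
  params = list(min_duration = 10))

test_that("the pipeline reports the scripted between-condition direction", {
  out_dir <- withr::local_tempdir()
  res <- run_pipeline(pipeline_config(), out_dir, make_figures = FALSE)
  expect_equal(length(res$failures), 0L)
  wt <- res$summaries$WT$acquisition_mean$eaten_per_cell
  ftd <- res$summaries$FTD$acquisition_mean$eaten_per_cell
  expect_gt(ftd, wt)  # condition B eats more by construction
  expect_true(all(c("statistic", "p_value", "annotation") %in%
                    names(res$comparison)))
  # intermediate artifacts persisted per scene
  expect_true(file.exists(file.path(out_dir, "WT", "scene01",
                                    "registration.csv")))
  expect_true(file.exists(file.path(out_dir, "WT", "scene01",
                                    "phagocytosis_events.csv")))
  expect_true(file.exists(file.path(out_dir, "condition_summary.csv")))
})

test_that("re-running the pipeline reproduces every CSV byte-for-byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- list(conditions = list(list(name = "WT", scenes = list(
    list(frame_size = 192L, n_frames = 10L, n_cells = 3L, n_aggregates = 6L,
         phagocytosis_events = list(list(1, 5, "shrink")),
         rng_seed = 55L)))),
    params = list(min_duration = 10))
  run_pipeline(cfg, d1, make_figures = FALSE)
  run_pipeline(cfg, d2, make_figures = FALSE)
  csvs <- list.files(d1, pattern = "\\.csv$", recursive = TRUE)
  expect_gt(length(csvs), 4L)
  for (f in csvs)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("a single-condition run produces summaries without a comparison", {
  out_dir <- withr::local_tempdir()
  cfg <- list(conditions = list(list(name = "only", scenes = list(
    list(frame_size = 192L, n_frames = 10L, n_cells = 3L, n_aggregates = 6L,
         rng_seed = 66L)))),
    params = list(min_duration = 10))
  res <- run_pipeline(cfg, out_dir, make_figures = FALSE)
  expect_null(res$comparison)
  expect_equal(length(res$summaries), 1L)
})

test_that("a broken scene is isolated while the run continues", {
  out_dir <- withr::local_tempdir()
  cfg <- list(conditions = list(list(name = "c", scenes = list(
    list(frame_size = 192L, n_frames = 10L, n_cells = 3L, n_aggregates = 6L,
         rng_seed = 66L),
    list(frame_size = -5L, n_frames = 10L)))),
    params = list(min_duration = 10))
  res <- run_pipeline(cfg, out_dir, make_figures = FALSE)
  expect_equal(length(res$failures), 1L)
  expect_equal(length(res$series), 1L)
  expect_true(file.exists(file.path(out_dir, "failures.json")))
})
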