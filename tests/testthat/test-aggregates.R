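test_that("threshold segmentation is strict: the boundary value is background", {
  f <- matrix(c(0, 0.4999, 0.5, 0.5001, 0.9, 1), 2, 3)
  m <- segment_aggregates(f)
  expect_equal(as.vector(m), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_false(any(segment_aggregates(matrix(0, 8, 8))))
})

test_that("a bright disk segments to exactly its own pixels", {
  sc <- generate_scene(scene_config(frame_size = 128L, n_frames = 2L,
                                    n_cells = 0L, n_aggregates = 3L,
                                    noise_level = 0, rng_seed = 31L))
  nrm <- normalize_stack(sc$aggregates, "aggregate")
  m <- segment_aggregates(get_frame(nrm$stack, 1L))
  expect_identical(m, sc$truth$aggregate_masks[[1L]] > 0)
})

test_that("labeling and measurement count pixels and centroids by hand", {
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE
  m[8:10, 7:9] <- TRUE
  tab <- label_and_measure(m, pixel_size = 0.103)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$area_px, c(9L, 9L))
  expect_equal(tab$area_um2, rep(9 * 0.103^2, 2), tolerance = 1e-12)
  expect_equal(tab$row[1], 2)  # 0-based mean of rows 2:4 -> (1+2+3)/3
  expect_equal(label_and_measure(matrix(FALSE, 5, 5))$label, integer(0))
  one <- matrix(FALSE, 5, 5); one[3, 4] <- TRUE
  t1 <- label_and_measure(one)
  expect_equal(t1$area_px, 1L)
  expect_equal(c(t1$row, t1$col), c(2, 3))
})

test_that("labeling honours 8-connectivity by default", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(nrow(label_and_measure(m)), 1L)
  expect_equal(nrow(label_and_measure(m, connectivity = 4L)), 2L)
})

test_that("the displacement threshold converts micrometers to pixels", {
  expect_identical(displacement_threshold_px(0.7, 0.103), 7L)
  expect_identical(displacement_threshold_px(0.7, 0.7), 1L)
  expect_identical(displacement_threshold_px(1.03, 0.103), 10L)
  expect_error(displacement_threshold_px(0.7, 0),
               class = "phagoquant_config_error")
})

test_that("label matching is by position, verified against brute force", {
  prev <- data.frame(label = 1:3, area_px = c(10, 20, 30),
                     row = c(5, 40, 80), col = c(5, 40, 80))
  expect_equal(match_labels(prev, prev)$cur_label, 1:3)
  # one aggregate gone
  cur <- prev[-2, ]
  mp <- match_labels(prev, cur)
  expect_equal(mp$cur_label, c(1L, NA, 3L))
  # labels permuted but positions static: matching must follow position;
  # oracle = assignment of minimal total distance over all permutations
  cur2 <- data.frame(label = c(2L, 3L, 1L), area_px = c(20, 30, 10),
                     row = c(40, 80, 5) + 0.4, col = c(40, 80, 5))
  mp2 <- match_labels(prev, cur2)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  cost <- vapply(perms, function(p)
    sum(sqrt((prev$row - cur2$row[p])^2 + (prev$col - cur2$col[p])^2)),
    numeric(1))
  best <- perms[[which.min(cost)]]
  expect_equal(mp2$cur_label, cur2$label[best])
})

test_that("phagocytosis fires on area halving or 7-px movement, not otherwise", {
  prev <- data.frame(label = 1L, area_px = 100, row = 10, col = 10)
  mk_cur <- function(area, dr) data.frame(label = 1L, area_px = area,
                                          row = 10 + dr, col = 10)
  mp <- function(cur) match_labels(prev, cur)
  ev <- detect_phagocytosis(prev, mk_cur(49, 0), mp(mk_cur(49, 0)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$criterion, "area")
  expect_equal(nrow(detect_phagocytosis(prev, mk_cur(80, 0),
                                        mp(mk_cur(80, 0)))), 0L)
  cur <- data.frame(label = 1L, area_px = 95, row = 18, col = 10)
  ev3 <- detect_phagocytosis(prev, cur, match_labels(prev, cur, max_radius = 15))
  expect_equal(ev3$criterion, "movement")  # 8 px >= 7 px
  # AND rule requires both
  expect_equal(nrow(detect_phagocytosis(prev, cur,
                                        match_labels(prev, cur, max_radius = 15),
                                        rule = "and")), 0L)
  cur4 <- data.frame(label = 1L, area_px = 40, row = 18, col = 10)
  ev4 <- detect_phagocytosis(prev, cur4, match_labels(prev, cur4, max_radius = 15),
                             rule = "and")
  expect_equal(ev4$criterion, "area+movement")
})

test_that("small vanished aggregates count as swallowed whole", {
  prev <- data.frame(label = 1:2, area_px = c(20, 200),
                     row = c(5, 50), col = c(5, 50))
  cur <- prev[2, ]
  ev <- detect_phagocytosis(prev, cur, match_labels(prev, cur))
  expect_equal(ev$criterion, "vanished")
  expect_equal(ev$area_before, 20)
})

test_that("cumulative eaten area is monotone and credits initial areas once", {
  tables <- data.frame(frame = rep(1:3, each = 2), label = rep(1:2, 3),
                       area_px = c(50, 60, 50, 25, 50, 12),
                       row = 0, col = 0)
  events <- data.frame(track = 2L, frame = 2L, criterion = "area",
                       area_before = 60, area_after = 25, displacement = 0,
                       area_credited_px = 60)
  ser <- aggregate_time_series(tables, events, 1:3, pixel_size = 1)
  expect_equal(ser$eaten_px, c(0, 60, 60))
  expect_true(all(diff(ser$eaten_px) >= 0))
  ser0 <- aggregate_time_series(tables, events[0, ], 1:3)
  expect_true(all(ser0$eaten_px == 0))
})

test_that("scripted events are recovered with their aggregates and frames", {
  sc <- event_scene()
  nrm <- normalize_stack(sc$aggregates, "aggregate")
  reg <- register_stack(nrm$stack, cascade_schedule(3, base_kernel = 65L))
  agg <- quantify_aggregates(reg$aligned)
  expect_equal(nrow(agg$events), 2L)
  # frames match the script within one frame
  expect_true(all(abs(sort(agg$events$frame) - sort(sc$truth$events$frame)) <= 1))
  # each detected track sits where a scripted aggregate was at frame 1
  tab1 <- sc$truth$aggregate_tables[sc$truth$aggregate_tables$frame == 1, ]
  truth_ids <- sc$truth$events$id[order(sc$truth$events$frame)]
  ord <- order(agg$events$frame)
  for (i in seq_len(2)) {
    tr <- agg$events$track[ord[i]]
    det <- agg$tables[agg$tables$frame == 1 & agg$tables$track == tr, ]
    gt <- tab1[tab1$id == truth_ids[i], ]
    expect_lt(sqrt((det$row - gt$row)^2 + (det$col - gt$col)^2), 2)
  }
  # eaten curve steps by the initial areas of the scripted aggregates
  eaten_final <- tail(agg$series$eaten_px, 1)
  gt_areas <- tab1$area_px[tab1$id %in% sc$truth$events$id]
  expect_equal(eaten_final, sum(gt_areas), tolerance = 0.1)
})

test_that("noiseless segmentation reproduces ground-truth masks pixel-exactly", {
  sc <- generate_scene(scene_config(frame_size = 160L, n_frames = 4L,
                                    n_cells = 0L, n_aggregates = 6L,
                                    noise_level = 0, rng_seed = 33L))
  nrm <- normalize_stack(sc$aggregates, "aggregate")
  for (t in 1:4) {
    m <- segment_aggregates(get_frame(nrm$stack, t))
    expect_identical(m, sc$truth$aggregate_masks[[t]] > 0)
  }
})
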