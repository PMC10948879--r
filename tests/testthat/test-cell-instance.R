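test_that("the classical backend scores cell interiors high and background low", {
  blank <- matrix(0.5, 96, 96)
  expect_lt(max(backend_prob(classical_backend(), blank)), 0.5)
  sc <- default_scene()
  nrm <- normalize_stack(sc$cells, "cell")
  p <- backend_prob(classical_backend(), get_frame(nrm$stack, 1L))
  gt <- sc$truth$cell_masks[[1L]]
  am <- arrayInd(which.max(p), dim(p))
  expect_true(gt[am[1], am[2]] > 0)  # argmax inside a cell
  expect_gt(mean(p[gt > 0]), 0.6)
  expect_lt(mean(p[gt == 0]), 0.25)
})

test_that("touching blobs leave a probability valley at their contact line", {
  # two overlapping disks: the waist has a smaller distance to background,
  # so the shaped probability dips along the contact line
  f <- matrix(0, 80, 80)
  d2 <- function(r0, c0) outer((1:80) - r0, rep(1, 80))^2 +
    outer(rep(1, 80), (1:80) - c0)^2
  fg <- d2(40, 28) <= 15^2 | d2(40, 54) <= 15^2
  dt <- as.matrix(EBImage::distmap(fg))
  prob <- ifelse(fg, 0.55 + 0.45 * pmin(dt / (0.6 * max(dt)), 1), 0)
  valley <- prob[40, 41]
  expect_lt(valley, prob[40, 28] - 0.05)
  expect_lt(valley, prob[40, 54] - 0.05)
})

test_that("temporal coherence is the window mean with high-threshold seeds", {
  m <- matrix(0, 20, 20)
  m[5:8, 5:8] <- 1
  m[14:16, 12:15] <- 1
  fused <- ttcm(list(m, m, m))
  expect_identical(fused$coherence, m)
  expect_equal(nrow(fused$seeds), 2L)
  # 3-of-5 presence gives coherence 0.6: below the 0.9 seed threshold
  z <- matrix(0, 20, 20)
  win <- list(m, m, m, z, z)
  f2 <- ttcm(win)
  expect_equal(max(f2$coherence), 0.6)
  expect_equal(nrow(f2$seeds), 0L)
  expect_equal(nrow(ttcm(win, seed_threshold = 0.5)$seeds), 2L)
  expect_error(ttcm(list()), class = "phagoquant_config_error")
})

test_that("seed regions shrink monotonically as the threshold rises", {
  sc <- default_scene()
  nrm <- normalize_stack(sc$cells, "cell")
  maps <- lapply(1:4, function(i)
    backend_prob(classical_backend(), get_frame(nrm$stack, i)))
  sizes <- vapply(c(0.5, 0.7, 0.9, 0.95), function(th)
    sum(ttcm(maps, seed_threshold = th)$seed_labels > 0), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("watershed grows one instance per seed and partitions the foreground", {
  f <- matrix(0, 60, 60)
  d2 <- function(r0, c0) outer((1:60) - r0, rep(1, 60))^2 +
    outer(rep(1, 60), (1:60) - c0)^2
  blob <- d2(30, 30) <= 12^2
  prob <- ifelse(blob, 0.95, 0.05)
  seeds <- matrix(0L, 60, 60)
  seeds[30, 30] <- 1L
  lab <- watershed_instances(prob, seeds)
  expect_identical(lab == 1L, blob)
  # two-lobed blob with a valley: the cut follows the valley column
  fg <- d2(30, 20) <= 11^2 | d2(30, 40) <= 11^2
  dt <- as.matrix(EBImage::distmap(fg))
  prob2 <- ifelse(fg, 0.55 + 0.45 * dt / max(dt), 0)
  seeds2 <- matrix(0L, 60, 60)
  seeds2[30, 20] <- 1L
  seeds2[30, 40] <- 2L
  lab2 <- watershed_instances(prob2, seeds2)
  expect_setequal(unique(lab2[fg]), c(1L, 2L))
  expect_equal(sum(fg & lab2 == 0), 0)  # full partition
  expect_true(all(lab2[30, 12:27] == 1L))
  expect_true(all(lab2[30, 33:48] == 2L))
  left_cols <- col(lab2)[lab2 == 1L]
  right_cols <- col(lab2)[lab2 == 2L]
  expect_lt(max(left_cols), min(right_cols) + 2)  # boundary near the waist
  # no seeds: empty labels, foreground reported unassigned
  lab3 <- watershed_instances(prob, matrix(0L, 60, 60))
  expect_equal(max(lab3), 0L)
  expect_equal(attr(lab3, "unassigned"), sum(blob))
  # seed outside foreground is dropped with a warning
  seeds4 <- seeds
  seeds4[2, 2] <- 2L
  expect_warning(watershed_instances(prob, seeds4), "outside")
})

test_that("border masks follow the dilate-subtract-dilate recipe", {
  expect_false(any(border_mask(matrix(FALSE, 10, 10))))
  expect_false(any(border_mask(matrix(TRUE, 10, 10))))
  # single-pixel oracle via independent shift-OR morphology
  m <- matrix(FALSE, 15, 15)
  m[8, 8] <- TRUE
  oracle <- dilate_oracle(dilate_oracle(m, 2) & !m, 4)
  expect_identical(border_mask(m), oracle)
  # a square block, same oracle
  b <- matrix(FALSE, 20, 20)
  b[8:12, 9:13] <- TRUE
  expect_identical(border_mask(b), dilate_oracle(dilate_oracle(b, 2) & !b, 4))
})

test_that("the alpha factor is the background-to-foreground pixel ratio", {
  half <- matrix(c(TRUE, FALSE), 10, 10)
  expect_equal(alpha_factor(half), 1)
  q <- matrix(FALSE, 10, 10)
  q[1:5, 1:5] <- TRUE
  expect_equal(alpha_factor(q), 3)
  one <- matrix(FALSE, 10, 10)
  one[5, 5] <- TRUE
  expect_equal(alpha_factor(one), 99)
  expect_error(alpha_factor(matrix(FALSE, 4, 4)),
               class = "phagoquant_degenerate_error")
})

test_that("the global loss matches its closed forms", {
  gt <- matrix(c(TRUE, FALSE), 8, 8)
  perfect <- ifelse(gt, 1, 0)
  expect_lt(loss_global(perfect, gt), 1e-5)
  # uniform 0.5 prediction, balanced mask, alpha 1: -log(0.5) per pixel
  expect_equal(loss_global(matrix(0.5, 8, 8), gt, alpha = 1), log(2),
               tolerance = 1e-12)
  # the background term scales linearly in alpha
  pred <- matrix(0.3, 8, 8)
  l1 <- loss_global(pred, gt, alpha = 1)
  l2 <- loss_global(pred, gt, alpha = 2)
  bg_term <- -mean((1 - gt) * log(1 - pred))
  expect_equal(l2 - l1, bg_term, tolerance = 1e-12)
})

test_that("the border loss is coverage of the true border", {
  border <- matrix(FALSE, 10, 10)
  border[4:6, 4:7] <- TRUE  # 12 border pixels
  off <- matrix(FALSE, 10, 10); off[1, 1] <- TRUE
  expect_equal(loss_border(off, border), 0)
  expect_equal(loss_border(matrix(TRUE, 10, 10), border), 1)
  part <- matrix(FALSE, 10, 10); part[4, 4:6] <- TRUE  # 3 of 12
  expect_equal(loss_border(part, border), 0.25)
  expect_error(loss_border(off, matrix(FALSE, 10, 10)),
               class = "phagoquant_degenerate_error")
})

test_that("the combined loss mixes with omega confined to [0, 0.5]", {
  expect_equal(total_loss(0.7, 0.2, omega = 0), 0.2)
  expect_equal(total_loss(0.5, 0.25, omega = 0.4), 0.4 * 0.5 + 0.6 * 0.25)
  expect_error(total_loss(0.5, 0.25, omega = 0.6),
               class = "phagoquant_config_error")
  # monotone in each component
  expect_gt(total_loss(0.6, 0.25), total_loss(0.5, 0.25))
  expect_gt(total_loss(0.5, 0.3), total_loss(0.5, 0.25))
})

test_that("mean activation heatmaps average channels and normalize range", {
  flat <- replicate(3, matrix(2, 8, 8), simplify = FALSE)
  expect_equal(mean_activation_heatmap(flat), matrix(0.5, 8, 8))
  a <- matrix(runif(64), 8, 8)
  hm <- mean_activation_heatmap(list(a, matrix(0, 8, 8)))
  m <- a / 2
  expect_equal(hm, (m - min(m)) / (max(m) - min(m)), tolerance = 1e-12)
  up <- mean_activation_heatmap(list(a), out_size = 16L)
  expect_equal(dim(up), c(16L, 16L))
  expect_gte(min(up), 0)
  expect_lte(max(up), 1)
})

test_that("scene segmentation recovers the true cell count and overlaps well", {
  sc <- default_scene()
  nrm <- normalize_stack(sc$cells, "cell")
  seg <- segment_scene(nrm$stack)
  counts <- table(seg$features$frame)
  expect_true(all(counts == 8L))
  expect_gte(mean_iou(seg$labels, sc$truth$cell_masks), 0.7)
  # instance labels partition the foreground of each frame
  lab <- seg$labels[[1L]]
  expect_equal(attr(lab, "unassigned"), 0L)
  # coherence recorded per instance, in [0, 1]
  expect_true(all(seg$features$coherence >= 0 & seg$features$coherence <= 1))
})

test_that("a single-frame window reduces to per-frame watershed", {
  sc <- default_scene()
  nrm <- normalize_stack(sc$cells, "cell")
  p1 <- backend_prob(classical_backend(), get_frame(nrm$stack, 1L))
  fused <- ttcm(list(p1))
  expect_identical(fused$coherence, p1)
  seg <- segment_scene(nrm$stack, accepted_frames = 1L, window = 1L)
  expect_equal(nrow(seg$features[seg$features$frame == 1, ]), 8L)
})
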