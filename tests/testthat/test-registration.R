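test_that("the kernel-size/sigma relation matches its closed form", {
  expect_equal(round(gaussian_sigma(513), 1), 77.3)
  expect_equal(round(gaussian_sigma(257), 1), 38.9)
  expect_equal(gaussian_sigma(3), 0.3 * ((3 - 1) * 0.5 - 1) + 0.8)
  expect_error(gaussian_sigma(4), class = "phagoquant_config_error")
  expect_error(gaussian_sigma(-1), class = "phagoquant_config_error")
})

test_that("the default cascade halves kernel sizes and ends on raw frames", {
  sch <- cascade_schedule()
  expect_equal(sch$kernel_size, c(513L, 257L, 129L, 65L, NA))
  expect_true(is.na(sch$sigma[5]))
  expect_true(all(diff(sch$kernel_size[1:4]) < 0))
})

test_that("ECC finds the identity on identical frames", {
  img <- blob_image()
  res <- ecc_translation(img, img)
  expect_true(res$converged)
  expect_lt(max(abs(res$shift)), 1e-4)
})

test_that("ECC recovers a known sub-pixel shift within 0.1 px", {
  img <- blob_image()
  mov <- apply_translation(img, c(5.0, -3.0))
  res <- ecc_translation(img, mov)
  expect_lt(abs(res$shift[["dx"]] - 5.0), 0.1)
  expect_lt(abs(res$shift[["dy"]] + 3.0), 0.1)
})

test_that("flat frames do not converge (zero gradient)", {
  flat <- matrix(1, 64, 64)
  res <- ecc_translation(flat, flat)
  expect_false(res$converged)
})

test_that("translation warps are exact for integer shifts and invertible", {
  img <- blob_image()
  expect_identical(apply_translation(img, c(0, 0)), img)
  sh <- apply_translation(img, c(3, -2))
  # integer shift equals an index-shifted copy on the valid region
  expect_equal(sh[1:(nrow(img) - 2), 4:ncol(img)],
               img[3:nrow(img), 1:(ncol(img) - 3)])
  # sub-pixel round trip: two bilinear warps act as a mild smoother, so
  # compare on a smooth image at interpolation tolerance
  smooth <- gaussian_smooth(img, sigma = 2)
  back <- apply_translation(apply_translation(smooth, c(4.5, 2.5)),
                            c(-4.5, -2.5))
  inner <- 10:(nrow(img) - 10)
  expect_lt(max(abs(back[inner, inner] - smooth[inner, inner])), 0.05)
})

test_that("cascade registration is exact on identical frames", {
  img <- blob_image()
  sch <- cascade_schedule(3, base_kernel = 65L)
  tr <- cecc_register(img, img, sch)
  expect_true(tr$converged)
  expect_lt(max(abs(tr$shift)), 1e-3)
  expect_equal(nrow(tr$levels), 3L)
})

test_that("swapping reference and moving negates the recovered shift", {
  img <- blob_image()
  mov <- apply_translation(img, c(7.3, -4.6))
  sch <- cascade_schedule(3, base_kernel = 65L)
  ab <- cecc_register(img, mov, sch)$shift
  ba <- cecc_register(mov, img, sch)$shift
  expect_lt(max(abs(ab + ba)), 0.05)
})

test_that("cascade error shrinks with level on synthetic blobs", {
  img <- blob_image(n = 256L, n_blobs = 30L, seed = 9L)
  sch <- cascade_schedule(4, base_kernel = 129L)
  errs <- sapply(1:5, function(i) {
    sh <- withr::with_seed(i, runif(2, -20, 20))
    tr <- cecc_register(img, apply_translation(img, sh), sch)
    abs(tr$levels$dx - sh[1]) + abs(tr$levels$dy - sh[2])
  })
  med <- apply(errs, 1, median)
  # median per-level error is non-increasing from the coarsest to the raw level
  expect_true(all(diff(med) <= 1e-6))
})

test_that("recovered shifts show no directional bias over symmetric draws", {
  img <- blob_image(n = 256L, n_blobs = 30L, seed = 9L)
  sch <- cascade_schedule(3, base_kernel = 65L)
  signed <- t(sapply(1:8, function(i) {
    sh <- withr::with_seed(100 + i, runif(2, -15, 15))
    cecc_register(img, apply_translation(img, sh), sch)$shift - sh
  }))
  # sign test: errors this tiny must straddle zero rather than pile one side
  expect_lt(max(abs(signed)), 0.05)
  for (ax in 1:2) {
    ns <- sum(signed[, ax] > 0)
    expect_gte(ns, 1)
    expect_lte(ns, 7)
  }
})

test_that("stack registration recovers an injected shift schedule", {
  sc <- event_scene()
  nrm <- normalize_stack(sc$aggregates, "aggregate")
  reg <- register_stack(nrm$stack, cascade_schedule(3, base_kernel = 65L))
  est <- reg$records[, c("dx", "dy")]
  truth <- sc$truth$shifts[, c("dx", "dy")]
  expect_lt(max(abs(est - truth)), 0.5)
  # aligned frames: the shifted frame is warped back onto the reference
  a5 <- get_frame(reg$aligned, 5L)
  a4 <- get_frame(reg$aligned, 4L)
  inner <- 30:220
  expect_lt(mean(abs(a5[inner, inner] - a4[inner, inner])), 2.5)
})

test_that("an all-identical stack registers to zero everywhere", {
  f <- blob_image(n = 96L, n_blobs = 8L, seed = 2L)
  stack <- frame_stack_memory(list(f, f, f))
  reg <- register_stack(stack, cascade_schedule(2, base_kernel = 33L))
  expect_lt(max(abs(reg$records[, c("dx", "dy")])), 1e-3)
  expect_true(all(reg$records$converged))
})

test_that("a degenerate frame is flagged without derailing the stack", {
  f <- blob_image(n = 96L, n_blobs = 8L, seed = 2L)
  stack <- frame_stack_memory(list(f, matrix(0, 96, 96), f))
  reg <- register_stack(stack, cascade_schedule(2, base_kernel = 33L))
  expect_false(reg$records$converged[2])
  expect_true(reg$records$converged[3])
  expect_lt(max(abs(reg$records[3, c("dx", "dy")])), 1e-3)
})

test_that("registration records round-trip through CSV", {
  f <- blob_image(n = 96L, n_blobs = 8L, seed = 2L)
  stack <- frame_stack_memory(list(f, apply_translation(f, c(2, 1))))
  reg <- register_stack(stack, cascade_schedule(2, base_kernel = 33L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_registration(reg$records, path)
  back <- read.csv(path)
  expect_equal(back$dx, reg$records$dx, tolerance = 1e-9)
  expect_true(grepl("\"level\"", back$level_trace[2]))
})
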