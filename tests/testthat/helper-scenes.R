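# Shared synthetic scenes, generated once per test run and cached.
.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.scene_cache[[key]])) .scene_cache[[key]] <- force(expr)
  .scene_cache[[key]]
}

# default study-condition scene (generator defaults; 8 frames for speed)
default_scene <- function() cached("default", {
  generate_scene(scene_config(n_frames = 8L))
})

# scene with scripted artifacts and phagocytosis events
event_scene <- function() cached("events", {
  generate_scene(scene_config(
    frame_size = 256L, n_frames = 16L, n_cells = 4L, n_aggregates = 8L,
    shift_schedule = list(c(5, 6, -4)),
    phagocytosis_events = list(list(2, 7, "shrink"), list(5, 11, "jump")),
    rng_seed = 7L))
})

# smooth blob image for registration unit tests
blob_image <- function(n = 192L, n_blobs = 20L, seed = 5L) {
  key <- sprintf("blob_%d_%d_%d", n, n_blobs, seed)
  cached(key, {
    withr::with_seed(seed, {
      img <- matrix(0, n, n)
      for (i in seq_len(n_blobs)) {
        r0 <- runif(1, 25, n - 25); c0 <- runif(1, 25, n - 25)
        s <- runif(1, 3, 8); a <- runif(1, 0.4, 1)
        rr <- outer(0:(n - 1) - r0, rep(1, n))
        cc <- outer(rep(1, n), 0:(n - 1) - c0)
        img <- img + a * exp(-(rr^2 + cc^2) / (2 * s^2))
      }
      img + matrix(rnorm(n * n, 0, 0.005), n, n)
    })
  })
}

# independent brute-force morphology oracle: 3x3 box dilation as OR of the
# 9 shifted copies
dilate_oracle <- function(mask, iterations = 1L) {
  out <- mask
  for (k in seq_len(iterations)) {
    nr <- nrow(out); nc <- ncol(out)
    acc <- matrix(FALSE, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
      ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
      acc[ok_r, ok_c] <- acc[ok_r, ok_c] | out[src_r[ok_r], src_c[ok_c]]
    }
    out <- acc
  }
  out
}
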