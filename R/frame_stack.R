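#' Time-ordered gray-level frame stack with delayed per-frame access
#'
#' A `frame_stack` is the container used for one channel of one scene: an
#' ordered accessor from frame index to a gray-level image (numeric matrix,
#' `[row, col]`), plus acquisition metadata (physical pixel size and frame
#' interval). The contract is *delayed reading*: accessing frame `i` must not
#' require materializing any other frame, so a full pass over a long sequence
#' keeps a constant number of frames resident.
#'
#' @param read_frame function taking a 1-based frame index and returning a
#'   numeric matrix.
#' @param n_frames number of frames in the stack.
#' @param frame_size integer side lengths `c(rows, cols)` shared by all frames.
#' @param bit_depth nominal bit depth of the stored intensities (8 or 16).
#' @param pixel_size physical pixel size, micrometers per pixel.
#' @param frame_interval acquisition interval between frames, minutes.
#'
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(read_frame, n_frames, frame_size,
                        bit_depth = 8L, pixel_size = 0.103,
                        frame_interval = 2) {
  if (!is.function(read_frame)) stop_config("'read_frame' must be a function")
  if (n_frames < 1) stop_config("'n_frames' must be >= 1")
  if (pixel_size <= 0) stop_config("'pixel_size' must be > 0")
  counter <- new.env(parent = emptyenv())
  counter$reads <- 0L
  structure(
    list(read_frame = read_frame, n_frames = as.integer(n_frames),
         frame_size = as.integer(rep_len(frame_size, 2L)),
         bit_depth = as.integer(bit_depth), pixel_size = pixel_size,
         frame_interval = frame_interval, .counter = counter),
    class = "frame_stack")
}

#' In-memory frame stack
#'
#' Wraps a list of equally-shaped numeric matrices as a [frame_stack()]. Used
#' for synthetic scenes and for small intermediate results.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @inheritParams frame_stack
#' @return A `frame_stack`.
#' @export
frame_stack_memory <- function(frames, bit_depth = 8L, pixel_size = 0.103,
                               frame_interval = 2) {
  if (!length(frames)) stop_config("'frames' must be a non-empty list")
  dims <- dim(frames[[1L]])
  ok <- vapply(frames, function(f) identical(dim(f), dims), logical(1))
  if (!all(ok)) stop_config("all frames must share the same shape")
  frame_stack(function(i) frames[[i]], length(frames), dims,
              bit_depth = bit_depth, pixel_size = pixel_size,
              frame_interval = frame_interval)
}

#' Directory-backed frame stack (single-page TIFF per frame)
#'
#' Reads frames lazily from a directory of single-page TIFF files named
#' `t0000.tif`, `t0001.tif`, ... (zero-based time index). Only the requested
#' frame is read from disk, honouring the delayed-reading contract.
#'
#' @param dir directory containing the frame files.
#' @param pattern regular expression selecting frame files; files are ordered
#'   lexicographically.
#' @inheritParams frame_stack
#' @return A `frame_stack`.
#' @export
frame_stack_dir <- function(dir, pattern = "^t[0-9]+\\.tif+$",
                            bit_depth = 8L, pixel_size = 0.103,
                            frame_interval = 2) {
  if (!dir.exists(dir)) stop_config(sprintf("no such directory: '%s'", dir))
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop_config(sprintf("no frame files in '%s'", dir))
  first <- read_frame_tiff(files[[1L]], bit_depth)
  frame_stack(function(i) read_frame_tiff(files[[i]], bit_depth),
              length(files), dim(first), bit_depth = bit_depth,
              pixel_size = pixel_size, frame_interval = frame_interval)
}

read_frame_tiff <- function(path, bit_depth) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  storage.mode(img) <- "double"
  img
}

#' Access one frame of a stack
#'
#' @param stack a [frame_stack()].
#' @param i 1-based frame index.
#' @return The frame as a numeric matrix.
#' @export
get_frame <- function(stack, i) {
  if (!inherits(stack, "frame_stack")) stop_config("not a frame_stack")
  i <- as.integer(i)
  if (i < 1L || i > stack$n_frames)
    stop_config(sprintf("frame index %d out of range [1, %d]", i,
                        stack$n_frames))
  stack$.counter$reads <- stack$.counter$reads + 1L
  stack$read_frame(i)
}

#' Number of frame accesses performed on a stack
#'
#' Instrumentation used to verify the delayed-reading contract (one access per
#' frame in a streaming pass, no hidden whole-stack loads).
#'
#' @param stack a [frame_stack()].
#' @return Integer count of [get_frame()] calls.
#' @export
stack_read_count <- function(stack) stack$.counter$reads

#' Derive a stack by mapping a function over frames, lazily
#'
#' The returned stack applies `f` to each frame on access, preserving the
#' delayed-reading contract (no eager materialization).
#'
#' @param stack a [frame_stack()].
#' @param f function from frame matrix to frame matrix.
#' @param bit_depth bit depth of the mapped frames.
#' @param frame_size optional new `c(rows, cols)` if `f` changes the shape.
#' @return A `frame_stack`.
#' @export
stack_map <- function(stack, f, bit_depth = stack$bit_depth,
                      frame_size = stack$frame_size) {
  frame_stack(function(i) f(get_frame(stack, i)), stack$n_frames,
              frame_size, bit_depth = bit_depth,
              pixel_size = stack$pixel_size,
              frame_interval = stack$frame_interval)
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf(
    "frame_stack: %d frames of %dx%d px, %d-bit, %.3f um/px, %.4g min/frame\n",
    x$n_frames, x$frame_size[1L], x$frame_size[2L], x$bit_depth,
    x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Write a stack to a directory of single-page TIFF files
#'
#' Frames are written as `t0000.tif`, `t0001.tif`, ... 8-bit frames are
#' written as 8-bit gray TIFF; 16-bit as 16-bit. Intensities are assumed to be
#' on the nominal integer scale of the stack's bit depth.
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxval <- if (isTRUE(stack$unit_scale)) 1 else 2^stack$bit_depth - 1
  bps <- if (stack$bit_depth > 8L) 16L else 8L
  paths <- character(stack$n_frames)
  for (i in seq_len(stack$n_frames)) {
    fr <- pmin(pmax(get_frame(stack, i), 0), maxval) / maxval
    paths[i] <- file.path(dir, sprintf("t%04d.tif", i - 1L))
    tiff::writeTIFF(fr, paths[i], bits.per.sample = bps)
  }
  invisible(paths)
}
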