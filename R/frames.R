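#' Image frames and sequences
#'
#' `image_frame()` wraps a numeric matrix of intensities already on the
#' \[0, 1\] scale; [normalize_frame()] converts raw camera data onto that
#' scale first. `image_sequence()` collects frames into an ordered
#' time-lapse series; the segmentation pipeline operates on its consecutive
#' frame pairs.
#'
#' A fixed intensity scale matters because the flow-magnitude threshold Th
#' is compared against displacements solved from intensity gradients:
#' without normalization the same Th would mean different things for 8-bit
#' and 16-bit acquisitions of the same scene.
#'
#' @param pixels Numeric matrix (rows = image rows, columns = image
#'   columns) with finite values in \[0, 1\].
#' @param index Non-negative integer time index of the frame.
#' @param source_bit_depth Provenance tag: 8, 12, 16 or the string
#'   `"float"`.
#' @return An `image_frame`: the pixel matrix with class and metadata
#'   attributes.
#' @examples
#' f <- image_frame(matrix(runif(32 * 32), 32, 32))
#' dim(f)
#' @export
image_frame <- function(pixels, index = 0L, source_bit_depth = "float") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    .stopf("flowseg_invalid_frame", "pixels must be a numeric matrix")
  if (any(!is.finite(pixels)))
    .stopf("flowseg_invalid_frame", "pixels contain NaN/Inf values")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    .stopf("flowseg_invalid_frame", "frame must be at least 2x2")
  if (min(pixels) < 0 || max(pixels) > 1)
    .stopf("flowseg_invalid_frame",
           "pixel values must lie in [0, 1]; got range [%g, %g]",
           min(pixels), max(pixels))
  if (index < 0) .stopf("flowseg_invalid_frame", "index must be >= 0")
  structure(pixels,
            index = as.integer(index),
            source_bit_depth = source_bit_depth,
            class = c("image_frame", "matrix", "array"))
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d, t = %d, source depth = %s\n",
              nrow(x), ncol(x), attr(x, "index"),
              as.character(attr(x, "source_bit_depth"))))
  invisible(x)
}

#' Normalize raw pixel data to the common \[0, 1\] intensity scale
#'
#' Integer data are divided by the full-scale value `2^bit_depth - 1`;
#' floating-point data are min-max rescaled (a constant image maps to all
#' zeros, since it carries no contrast).
#'
#' @param raw_pixels Numeric matrix of raw intensities.
#' @param bit_depth 8, 12 or 16 for integer data, or `"float"`.
#' @inheritParams image_frame
#' @return An [image_frame()].
#' @examples
#' normalize_frame(matrix(255L, 4, 4), 8)[1, 1]  # 1.0
#' @export
normalize_frame <- function(raw_pixels, bit_depth, index = 0L) {
  if (!is.matrix(raw_pixels) || length(raw_pixels) == 0L)
    .stopf("flowseg_invalid_frame", "raw_pixels must be a nonempty matrix")
  if (any(!is.finite(raw_pixels)))
    .stopf("flowseg_invalid_frame", "raw_pixels contain NaN/Inf values")
  if (identical(bit_depth, "float")) {
    rng <- range(raw_pixels)
    px <- if (rng[1] == rng[2]) matrix(0, nrow(raw_pixels), ncol(raw_pixels))
          else (raw_pixels - rng[1]) / (rng[2] - rng[1])
    return(image_frame(px, index, "float"))
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 12L, 16L))
    .stopf("flowseg_invalid_frame", "bit_depth must be 8, 12, 16 or \"float\"")
  full <- 2^bit_depth - 1
  if (min(raw_pixels) < 0 || max(raw_pixels) > full)
    .stopf("flowseg_invalid_frame",
           "integer data out of range for %d-bit: [%g, %g]",
           bit_depth, min(raw_pixels), max(raw_pixels))
  image_frame(raw_pixels / full, index, bit_depth)
}

#' @rdname image_frame
#' @param frames List of `image_frame`s with identical dimensions and
#'   strictly increasing time indices.
#' @param frame_interval Positive time between frames in seconds
#'   (metadata only; flow is reported in pixels/frame).
#' @export
image_sequence <- function(frames, frame_interval = 1) {
  if (!is.list(frames) || length(frames) < 2L)
    .stopf("flowseg_invalid_sequence",
           "need >= 2 frames: the method is defined on consecutive pairs")
  ok <- vapply(frames, inherits, logical(1), "image_frame")
  if (!all(ok))
    .stopf("flowseg_invalid_sequence", "all elements must be image_frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    .stopf("flowseg_invalid_sequence",
           "all frames must share dimensions; frame %d is %dx%d, expected %dx%d",
           which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1],
           dims[1, which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]],
           dims[2, which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]],
           dims[1, 1], dims[2, 1])
  idx <- vapply(frames, function(f) attr(f, "index"), integer(1))
  if (any(diff(idx) <= 0L))
    .stopf("flowseg_invalid_sequence", "frame indices must be strictly increasing")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    .stopf("flowseg_invalid_sequence", "frame_interval must be positive")
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_sequence> %d frames of %d x %d, interval %g s\n",
              length(x$frames), d[1], d[2], x$frame_interval))
  invisible(x)
}

#' @export
length.image_sequence <- function(x) length(x$frames)
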