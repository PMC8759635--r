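#' Optical-flow estimation parameters
#'
#' Controls for the dense Farneback flow estimator. The defaults follow the
#' conventions common to widely used implementations of the method:
#' three pyramid levels halving resolution each time (each coarse pixel is
#' the average of a 2x2 group), a 5x5 polynomial-expansion window with a
#' Gaussian applicability of sd 1.1 weighting the fit towards the window
#' centre, a 15-pixel window for spatially averaging the displacement
#' normal equations, and three fixed-point iterations per level.
#'
#' @param pyramid_levels Number of resolution levels (level 1 is native
#'   resolution). The coarsest level must remain at least 8x8 pixels;
#'   [build_pyramid()] enforces this against the actual image size.
#' @param pyramid_scale Downsampling factor between levels; fixed at 0.5
#'   (2x2 pixel averaging).
#' @param expansion_window Odd side length, in pixels, of the neighbourhood
#'   fitted with a quadratic polynomial at every pixel.
#' @param expansion_sigma Standard deviation of the Gaussian applicability
#'   weighting the fit towards the window centre.
#' @param averaging_window Odd side length of the box window over which the
#'   displacement normal equations are averaged.
#' @param iterations_per_level Fixed-point iterations of the displacement
#'   update at each pyramid level.
#' @return A `flow_params` list.
#' @export
flow_params <- function(pyramid_levels = 3L, pyramid_scale = 0.5,
                        expansion_window = 5L, expansion_sigma = 1.1,
                        averaging_window = 15L, iterations_per_level = 3L) {
  if (pyramid_levels < 1L)
    .stopf("flowseg_invalid_params", "pyramid_levels must be >= 1")
  if (!identical(as.numeric(pyramid_scale), 0.5))
    .stopf("flowseg_invalid_params",
           "pyramid_scale is fixed at 0.5 (2x2 pixel averaging)")
  if (!.is_odd(as.integer(expansion_window)) || expansion_window < 3L)
    .stopf("flowseg_invalid_params", "expansion_window must be odd and >= 3")
  if (!.is_odd(as.integer(averaging_window)) || averaging_window < 1L)
    .stopf("flowseg_invalid_params", "averaging_window must be odd and >= 1")
  if (expansion_sigma <= 0)
    .stopf("flowseg_invalid_params", "expansion_sigma must be positive")
  if (iterations_per_level < 1L)
    .stopf("flowseg_invalid_params", "iterations_per_level must be >= 1")
  structure(list(pyramid_levels = as.integer(pyramid_levels),
                 pyramid_scale = 0.5,
                 expansion_window = as.integer(expansion_window),
                 expansion_sigma = expansion_sigma,
                 averaging_window = as.integer(averaging_window),
                 iterations_per_level = as.integer(iterations_per_level)),
            class = "flow_params")
}

#' One level of pyramid decimation: 2x2 block mean with ceiling sizing
#'
#' Each output pixel is the mean of its (up to) four source pixels; odd
#' trailing rows/columns form truncated blocks, so an `h x w` input yields
#' `ceil(h/2) x ceil(w/2)`. This is the bare decimation step; the pyramid
#' builder Gaussian-smooths before calling it to suppress aliasing.
#'
#' @param x Numeric matrix.
#' @return Numeric matrix of the decimated image.
#' @export
pyr_decimate <- function(x) {
  h <- nrow(x); w <- ncol(x)
  hh <- ceiling(h / 2); ww <- ceiling(w / 2)
  # sum within 2x2 blocks via row/col grouping, divide by actual block size
  rg <- (seq_len(h) + 1L) %/% 2L
  cg <- (seq_len(w) + 1L) %/% 2L
  sums <- rowsum(x, rg)                # collapse rows
  sums <- t(rowsum(t(sums), cg))       # collapse cols
  counts <- tabulate(rg, hh) %o% tabulate(cg, ww)
  out <- sums / counts
  dimnames(out) <- NULL
  out
}

#' Build the coarse-to-fine resolution pyramid for one frame
#'
#' Level 1 is the input frame; each further level is the 2x2 block mean of
#' the previous one ([pyr_decimate()]), preceded by a Gaussian pre-smooth
#' (sd 1) to suppress aliasing. The smoothing uses a mirrored image border
#' so that, for even dimensions, every level preserves its parent's mean
#' intensity exactly.
#'
#' @param frame An [image_frame()].
#' @param params A [flow_params()].
#' @return List of `image_frame`s, native resolution first, coarsest last.
#' @export
build_pyramid <- function(frame, params = flow_params()) {
  if (!inherits(frame, "image_frame"))
    .stopf("flowseg_invalid_frame", "frame must be an image_frame")
  h <- nrow(frame); w <- ncol(frame)
  # levels allowed so the coarsest stays >= 8x8
  max_levels <- 1L
  hh <- h; ww <- w
  repeat {
    hh2 <- ceiling(hh / 2); ww2 <- ceiling(ww / 2)
    if (hh2 < 8L || ww2 < 8L) break
    max_levels <- max_levels + 1L; hh <- hh2; ww <- ww2
  }
  if (params$pyramid_levels > max_levels)
    .stopf("flowseg_pyramid_too_deep",
           "pyramid_levels = %d leaves a coarsest level below 8x8 for a %dx%d image; maximum is %d",
           params$pyramid_levels, h, w, max_levels)
  k <- .gaussian_kernel(1)
  levels <- vector("list", params$pyramid_levels)
  levels[[1]] <- frame
  cur <- unclass(frame); attributes(cur) <- list(dim = dim(frame))
  for (lv in seq_len(params$pyramid_levels - 1L)) {
    sm <- .correlate_sep(cur, k, k, boundary = "mirror")
    cur <- pyr_decimate(sm)
    cur[cur < 0] <- 0; cur[cur > 1] <- 1  # guard rounding at the boundary
    levels[[lv + 1L]] <- image_frame(cur, attr(frame, "index"),
                                     attr(frame, "source_bit_depth"))
  }
  levels
}
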