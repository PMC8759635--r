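#' Flow-field container
#'
#' Per-pixel displacement between a consecutive frame pair, in pixels per
#' frame at the resolution of the source frames. `u` is the horizontal
#' component (across columns, positive rightward), `v` the vertical
#' component (down rows). The field is defined at every pixel, borders
#' included.
#'
#' @param u,v Numeric matrices of identical dimensions, finite everywhere.
#' @param pair_index Time index `t` of the earlier frame of the pair.
#' @return A `flow_field` list.
#' @export
flow_field <- function(u, v, pair_index = 0L) {
  if (!identical(dim(u), dim(v)))
    .stopf("flowseg_dim_mismatch", "u and v must share dimensions")
  if (any(!is.finite(u)) || any(!is.finite(v)))
    .stopf("flowseg_invalid_flow", "flow contains NaN/Inf")
  structure(list(u = u, v = v, pair_index = as.integer(pair_index)),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  m <- flow_magnitude(x)
  cat(sprintf("<flow_field> %d x %d, pair t = %d, |flow| max %.4g px/frame\n",
              nrow(x$u), ncol(x$u), x$pair_index, max(m)))
  invisible(x)
}

#' Per-pixel flow magnitude
#'
#' Euclidean norm \eqn{\sqrt{u^2 + v^2}} of the displacement field; this is
#' the quantity the segmentation threshold Th is compared against.
#'
#' @param field A [flow_field()].
#' @return Non-negative numeric matrix in pixels/frame.
#' @export
flow_magnitude <- function(field) {
  if (!inherits(field, "flow_field"))
    .stopf("flowseg_invalid_flow", "field must be a flow_field")
  sqrt(field$u^2 + field$v^2)
}

#' One level of iterative displacement estimation
#'
#' Given the polynomial expansions of two frames and a prior displacement
#' field, performs the Farneback fixed-point update: the prior `d` is used
#' to sample the second expansion at warped positions (nearest-pixel
#' rounding, border-clamped); the pointwise system `A d = db` with
#' `A = (A1 + A2_warped)/2` and `db = -(b2_warped - b1)/2 + A d_prior` is
#' averaged spatially (box window of side `averaging_window`) through its
#' normal equations, and the 2x2 system is solved at every pixel. The
#' update is repeated `iterations_per_level` times, feeding the solution
#' back as the prior. Pixels whose averaged system is near-singular
#' (determinant below 1e-12, e.g. constant regions with no gradient
#' information) keep the prior displacement.
#'
#' @param expA,expB `poly_expansion`s of the earlier and later frame.
#' @param prior A [flow_field()] used as the initial displacement.
#' @param params A [flow_params()].
#' @return A [flow_field()].
#' @export
estimate_displacement <- function(expA, expB, prior, params = flow_params()) {
  d <- attr(expA, "dims")
  if (!identical(d, attr(expB, "dims")) || !identical(d, dim(prior$u)))
    .stopf("flowseg_dim_mismatch",
           "expansions and prior must share dimensions")
  h <- d[1]; w <- d[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  kb <- .box_kernel(params$averaging_window)
  u <- prior$u; v <- prior$v

  for (it in seq_len(params$iterations_per_level)) {
    wr <- pmin.int(pmax.int(rows + round(v), 1L), h)
    wc <- pmin.int(pmax.int(cols + round(u), 1L), w)
    li <- (wc - 1L) * h + wr
    # displacement actually applied by the warp (rounded, border-clamped);
    # the compensation term must use it, not the fractional prior, or the
    # fixed point of the iteration drifts off the true displacement
    rdx <- wc - cols; rdy <- wr - rows

    axx <- (expA$axx + expB$axx[li]) / 2
    axy <- (expA$axy + expB$axy[li]) / 2
    ayy <- (expA$ayy + expB$ayy[li]) / 2
    dbx <- -0.5 * (expB$bx[li] - expA$bx) + axx * rdx + axy * rdy
    dby <- -0.5 * (expB$by[li] - expA$by) + axy * rdx + ayy * rdy

    # normal equations of A d = db, averaged over the window
    g11 <- .correlate_sep(axx^2 + axy^2,        kb, kb)
    g12 <- .correlate_sep(axy * (axx + ayy),    kb, kb)
    g22 <- .correlate_sep(axy^2 + ayy^2,        kb, kb)
    h1  <- .correlate_sep(axx * dbx + axy * dby, kb, kb)
    h2  <- .correlate_sep(axy * dbx + ayy * dby, kb, kb)

    det <- g11 * g22 - g12^2
    ok <- det >= 1e-12
    un <- u; vn <- v
    un[ok] <- (g22[ok] * h1[ok] - g12[ok] * h2[ok]) / det[ok]
    vn[ok] <- (g11[ok] * h2[ok] - g12[ok] * h1[ok]) / det[ok]
    u <- un; v <- vn
  }
  flow_field(u, v, prior$pair_index)
}

# Bilinear upsampling of a coarse grid to fine dimensions, aligned with the
# 2x2 block decimation (coarse pixel i is centred at fine coordinate 2i-0.5).
.upsample_bilinear <- function(x, h, w) {
  hc <- nrow(x); wc <- ncol(x)
  rf <- (seq_len(h) + 0.5) / 2
  cf <- (seq_len(w) + 0.5) / 2
  r0 <- pmin.int(pmax.int(floor(rf), 1L), hc); r1 <- pmin.int(r0 + 1L, hc)
  c0 <- pmin.int(pmax.int(floor(cf), 1L), wc); c1 <- pmin.int(c0 + 1L, wc)
  ar <- pmin(pmax(rf - r0, 0), 1)
  ac <- pmin(pmax(cf - c0, 0), 1)
  A <- x[r0, c0, drop = FALSE]; B <- x[r0, c1, drop = FALSE]
  C <- x[r1, c0, drop = FALSE]; D <- x[r1, c1, drop = FALSE]
  WR <- matrix(ar, h, w); WC <- matrix(ac, h, w, byrow = TRUE)
  (A * (1 - WR) + C * WR) * (1 - WC) + (B * (1 - WR) + D * WR) * WC
}

#' Dense Farneback optical flow between two consecutive frames
#'
#' Runs the full coarse-to-fine estimator: both frames are decomposed into
#' resolution pyramids ([build_pyramid()]); at the coarsest level the
#' displacement starts from zero, and at each finer level the previous
#' solution is bilinearly upsampled, its values doubled, and used as the
#' prior for [estimate_displacement()] on that level's polynomial
#' expansions. The result is a full-resolution displacement field in
#' pixels/frame.
#'
#' @param frame_t,frame_t1 Consecutive [image_frame()]s of equal size.
#' @param params A [flow_params()].
#' @return A [flow_field()] with `pair_index` set to `frame_t`'s index.
#' @examples
#' f <- image_frame(matrix(runif(64 * 64), 64, 64))
#' fl <- farneback_flow(f, f)
#' max(flow_magnitude(fl))  # ~0 for a static scene
#' @export
farneback_flow <- function(frame_t, frame_t1, params = flow_params()) {
  if (!identical(dim(frame_t), dim(frame_t1)))
    .stopf("flowseg_dim_mismatch", "frames must share dimensions")
  pyrA <- build_pyramid(frame_t, params)
  pyrB <- build_pyramid(frame_t1, params)
  nlev <- params$pyramid_levels
  u <- v <- NULL
  for (lv in seq.int(nlev, 1L)) {
    fa <- pyrA[[lv]]; fb <- pyrB[[lv]]
    h <- nrow(fa); w <- ncol(fa)
    if (is.null(u)) {
      u <- matrix(0, h, w); v <- matrix(0, h, w)
    } else {
      u <- 2 * .upsample_bilinear(u, h, w)
      v <- 2 * .upsample_bilinear(v, h, w)
    }
    expA <- polynomial_expansion(fa, params)
    expB <- polynomial_expansion(fb, params)
    fl <- estimate_displacement(expA, expB,
                                flow_field(u, v, attr(frame_t, "index")),
                                params)
    u <- fl$u; v <- fl$v
  }
  flow_field(u, v, attr(frame_t, "index"))
}
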