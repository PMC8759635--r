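# Shared fixtures and independent oracles. Everything here is deliberately
# naive (loops, dense solves, FFTs) so it cannot share a bug with the
# package's separable/vectorised implementations.

# Smooth random texture in [0.1, 0.9], smoothed *circularly* so that
# circular shifts of the result are exact translations of the same signal.
mk_smooth_texture <- function(n = 128, seed = 42, sigma = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * n), n, n)
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  idx <- function(i) ((i - 1) %% n) + 1
  for (margin in 1:2) {
    out <- matrix(0, n, n)
    for (t in -r:r) {
      w <- k[t + r + 1]
      out <- out + if (margin == 1) w * x[idx(seq_len(n) + t), ]
                   else w * x[, idx(seq_len(n) + t)]
    }
    x <- out
  }
  0.1 + 0.8 * (x - min(x)) / (max(x) - min(x))
}

# Circular integer shift: content moves down by dr and right by dc.
circ_shift <- function(m, dr, dc) {
  n <- nrow(m); w <- ncol(m)
  m[((seq_len(n) - dr - 1) %% n) + 1, ((seq_len(w) - dc - 1) %% w) + 1]
}

# Bandlimited (Fourier) subpixel shift; content moves by (dr, dc).
fft_shift <- function(m, dr, dc) {
  n <- nrow(m); stopifnot(ncol(m) == n, n %% 2 == 0)
  kk <- c(0:(n / 2 - 1), -(n / 2):-1)
  ph <- exp(-2i * pi * (outer(kk, rep(0, n), "+") * dr +
                        outer(rep(0, n), kk, "+") * dc) / n)
  Re(fft(fft(m) * ph, inverse = TRUE)) / length(m)
}

# Independent integer-shift estimator: FFT phase correlation peak.
phase_correlation_shift <- function(a, b) {
  R <- fft(a) * Conj(fft(b))
  R <- R / pmax(Mod(R), 1e-12)
  p <- Re(fft(R, inverse = TRUE))
  pk <- which(p == max(p), arr.ind = TRUE)[1, ]
  sh <- pk - 1L
  n <- nrow(a); w <- ncol(a)
  dr <- if (sh[1] > n / 2) sh[1] - n else sh[1]
  dc <- if (sh[2] > w / 2) sh[2] - w else sh[2]
  # peak at (-dr, -dc) convention: a(x) ~ b(x + d); resolve sign by testing
  c(dr = -unname(dr), dc = -unname(dc))
}

# Dense per-pixel weighted least-squares polynomial fit: the oracle for
# polynomial_expansion. Builds the full design matrix at one pixel, with
# edge replication, and solves with qr.solve.
wls_expansion_at <- function(img, r0, c0, window = 5, sigma = 1.1) {
  n <- (window - 1) / 2
  h <- nrow(img); w <- ncol(img)
  rows <- cols <- f <- wt <- numeric(0)
  for (dy in -n:n) for (dx in -n:n) {
    rr <- min(max(r0 + dy, 1), h)
    cc <- min(max(c0 + dx, 1), w)
    rows <- c(rows, dy); cols <- c(cols, dx)
    f <- c(f, img[rr, cc])
    wt <- c(wt, exp(-(dx^2) / (2 * sigma^2)) * exp(-(dy^2) / (2 * sigma^2)))
  }
  B <- cbind(1, cols, rows, cols^2, rows^2, cols * rows)
  sw <- sqrt(wt)
  r <- qr.solve(B * sw, f * sw)
  r <- unname(r)
  list(c = r[1], bx = r[2], by = r[3], axx = r[4], ayy = r[5], axy = r[6] / 2)
}

# Brute-force Z^2 set-definition morphology on the disk structuring
# element, written coordinate-wise straight from the definitions:
# dilation = union of translated copies of the set, erosion = points whose
# whole translated element lies inside the set.
bf_closing <- function(mask, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, , drop = FALSE]
  h <- nrow(mask); w <- ncol(mask); r <- radius
  H <- h + 2L * r; W <- w + 2L * r
  pad <- matrix(FALSE, H, W)
  pad[(r + 1):(r + h), (r + 1):(r + w)] <- mask
  dil <- matrix(FALSE, H, W)
  tp <- which(pad, arr.ind = TRUE)
  if (nrow(tp)) for (k in seq_len(nrow(offs))) {
    rr <- tp[, 1] + offs$dr[k]; cc <- tp[, 2] + offs$dc[k]
    keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    dil[cbind(rr[keep], cc[keep])] <- TRUE
  }
  ero <- matrix(FALSE, H, W)
  cand <- which(dil, arr.ind = TRUE)
  if (nrow(cand)) {
    ok <- rep(TRUE, nrow(cand))
    for (k in seq_len(nrow(offs))) {
      rr <- cand[, 1] + offs$dr[k]; cc <- cand[, 2] + offs$dc[k]
      inside <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      val <- inside
      val[inside] <- dil[cbind(rr[inside], cc[inside])]
      ok <- ok & val
    }
    ero[cand[ok, , drop = FALSE]] <- TRUE
  }
  ero[(r + 1):(r + h), (r + 1):(r + w)]
}

# Brute-force hole fill: BFS flood from all border background pixels with
# 4-connectivity; anything not reached becomes foreground.
bf_fill <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  reach <- matrix(FALSE, h, w)
  queue <- which(!mask & (row(mask) %in% c(1, h) | col(mask) %in% c(1, w)))
  reach[queue] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    r <- (p - 1) %% h + 1; c <- (p - 1) %/% h + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
        q <- (cc - 1) * h + rr
        if (!mask[q] && !reach[q]) { reach[q] <- TRUE; queue <- c(queue, q) }
      }
    }
  }
  mask | !reach
}

# Frame helpers
as_frame <- function(m, index = 0L) image_frame(m, index)

# A two-frame scene of a textured disk over a statically textured noisy
# background; returns frames plus the exact disk mask of frame 1.
disk_pair_fixture <- function(seed = 7, radius = 20, shift = c(0, 1.5)) {
  sc <- scene_spec(128, 128, 2,
                   cells = list(cell_spec(c(64, 60), base_radius = radius,
                                          velocity = shift,
                                          boundary_wobble_amplitude = 0,
                                          interior_texture_contrast = 0.18,
                                          texture_flicker_rate = 0)),
                   background = "flat", background_noise_sigma = 0.005,
                   background_texture_contrast = 0.10, rng_seed = seed)
  out <- render_scene(sc)
  list(f1 = out$sequence$frames[[1]], f2 = out$sequence$frames[[2]],
       disk = out$truth[[1]]$labels > 0)
}
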