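# Separable correlation primitives shared by the pyramid, the polynomial
# expansion and the displacement averaging. All operate on plain numeric
# matrices and are fully vectorised (shift-and-accumulate), so no compiled
# code is needed at the image sizes this package targets.

# Mirror ("symmetric", edge repeated) index: 0 -> 1, -1 -> 2, n+1 -> n, ...
# Valid while the kernel half-width is < dim, which all callers guarantee.
.mirror_idx <- function(idx, d) {
  idx <- ifelse(idx < 1L, 1L - idx, idx)
  ifelse(idx > d, 2L * d + 1L - idx, idx)
}

# 1-D correlation along one margin of a matrix.
# margin 1: kernel slides down the rows (vertical); margin 2: across columns.
# boundary "replicate" clamps indices (edge replication); "mirror" reflects,
# which conserves the image sum exactly for symmetric kernels.
.correlate1d <- function(x, k, margin, boundary = "replicate") {
  n <- (length(k) - 1L) %/% 2L
  d <- dim(x)[margin]
  out <- matrix(0, nrow(x), ncol(x))
  for (t in seq.int(-n, n)) {
    idx <- seq_len(d) + t
    idx <- if (boundary == "replicate") pmin.int(pmax.int(idx, 1L), d)
           else .mirror_idx(idx, d)
    w <- k[t + n + 1L]
    out <- out + if (margin == 1L) w * x[idx, , drop = FALSE]
                 else w * x[, idx, drop = FALSE]
  }
  out
}

# Separable 2-D correlation: kr along rows (y), kc along columns (x).
.correlate_sep <- function(x, kr, kc, boundary = "replicate") {
  .correlate1d(.correlate1d(x, kr, 1L, boundary), kc, 2L, boundary)
}

.gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  t <- seq.int(-radius, radius)
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

.box_kernel <- function(width) {
  stopifnot(width %% 2L == 1L)
  rep(1 / width, width)
}

# Shift a matrix by (dr, dc) padding with `fill`; used by morphology and tests.
.shift_matrix <- function(x, dr, dc, fill = 0) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  if (length(rs) > 0L && length(cs) > 0L)
    out[rs, cs] <- x[rs - dr, cs - dc, drop = FALSE]
  out
}

.is_odd <- function(x) x %% 2L == 1L

.stopf <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "flowseg_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
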