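#' Quadratic polynomial expansion of an image
#'
#' At every pixel, the local neighbourhood is approximated by the quadratic
#' model \eqn{f(x) = x^T A x + b^T x + c}, with `x = (dx, dy)` the offset
#' from the pixel (dx across columns, dy down rows). The fit is a weighted
#' least squares over an `expansion_window` square with a Gaussian
#' applicability (sd `expansion_sigma`) centred on the pixel, and is
#' computed for all pixels at once through separable correlations: the six
#' weighted moments of the image against the basis
#' \eqn{(1, x, y, x^2, y^2, xy)} are correlation images, and the (constant,
#' position-independent) 6x6 normal matrix is inverted once. The image is
#' extended by edge replication at its borders.
#'
#' @param frame An [image_frame()] (or plain numeric matrix).
#' @param params A [flow_params()]; `expansion_window` and
#'   `expansion_sigma` are used.
#' @return A `poly_expansion`: list of per-pixel coefficient matrices
#'   `axx`, `axy`, `ayy` (the symmetric A), `bx`, `by` (the gradient term)
#'   and `c` (the constant term), each with the frame's dimensions.
#' @export
polynomial_expansion <- function(frame, params = flow_params()) {
  f <- unclass(frame); attributes(f) <- list(dim = dim(frame))
  n <- (params$expansion_window - 1L) %/% 2L
  if (nrow(f) < params$expansion_window || ncol(f) < params$expansion_window)
    .stopf("flowseg_window_too_large",
           "expansion_window %d exceeds image size %dx%d",
           params$expansion_window, nrow(f), ncol(f))
  t <- seq.int(-n, n)
  g <- exp(-t^2 / (2 * params$expansion_sigma^2))
  g <- g / sum(g)
  gt <- g * t
  gt2 <- g * t^2

  # weighted moments of f against the basis (1, x, y, x^2, y^2, xy);
  # x varies along columns, y along rows
  m1  <- .correlate_sep(f, g,   g)
  mx  <- .correlate_sep(f, g,   gt)
  my  <- .correlate_sep(f, gt,  g)
  mx2 <- .correlate_sep(f, g,   gt2)
  my2 <- .correlate_sep(f, gt2, g)
  mxy <- .correlate_sep(f, gt,  gt)

  # normal matrix G[i,j] = sum w * basis_i * basis_j over the window
  w2 <- g %o% g
  X <- matrix(rep(t, each = length(t)), length(t))   # column offsets
  Y <- matrix(rep(t, times = length(t)), length(t))  # row offsets
  B <- cbind(1, as.vector(X), as.vector(Y),
             as.vector(X)^2, as.vector(Y)^2, as.vector(X) * as.vector(Y))
  G <- crossprod(B * as.vector(w2), B)
  Ginv <- solve(G)

  M <- rbind(as.vector(m1), as.vector(mx), as.vector(my),
             as.vector(mx2), as.vector(my2), as.vector(mxy))
  R <- Ginv %*% M
  d <- dim(f)
  shape <- function(v) matrix(v, d[1], d[2])
  structure(list(c   = shape(R[1, ]),
                 bx  = shape(R[2, ]),
                 by  = shape(R[3, ]),
                 axx = shape(R[4, ]),
                 ayy = shape(R[5, ]),
                 axy = shape(R[6, ] / 2)),
            dims = d, class = "poly_expansion")
}

#' @export
print.poly_expansion <- function(x, ...) {
  d <- attr(x, "dims")
  cat(sprintf("<poly_expansion> %d x %d quadratic coefficients\n", d[1], d[2]))
  invisible(x)
}
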