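#' Specification of one synthetic cell
#'
#' Cells are star-convex shapes whose boundary radius
#' \eqn{r(\theta, t) = R (1 + a \sum_{m=2}^{4} c_m \cos(m\theta + \phi_m + \omega t))}
#' deforms over time (low-order Fourier modes with phases advancing at the
#' wobble rate), filled with a smoothed noise texture that translates with
#' the cell and can additionally fluctuate in place — emulating the
#' intracellular intensity fluctuations that make even non-migrating cells
#' segmentable by motion.
#'
#' @param initial_centroid Numeric `(row, col)` of the cell centre in the
#'   first frame (0-based pixel coordinates).
#' @param base_radius Mean radius R in pixels (>= 3).
#' @param velocity Numeric `(rows/frame, cols/frame)` rigid translation of
#'   the centroid.
#' @param boundary_wobble_amplitude Fraction `a` of the radius taken by the
#'   boundary deformation, in `[0, 1)`.
#' @param boundary_wobble_rate Phase advance of the boundary modes in
#'   radians/frame.
#' @param interior_texture_contrast Amplitude of the interior texture on
#'   the \[0,1\] intensity scale.
#' @param texture_length_scale Gaussian smoothing sd of the texture noise,
#'   in pixels (its correlation length).
#' @param texture_flicker_rate Temporal fluctuation of the interior
#'   texture in cycles/frame; 0 freezes the texture in the cell's frame of
#'   reference so a stationary cell is truly static.
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(initial_centroid, base_radius, velocity = c(0, 0),
                      boundary_wobble_amplitude = 0.05,
                      boundary_wobble_rate = 0.2,
                      interior_texture_contrast = 0.15,
                      texture_length_scale = 3,
                      texture_flicker_rate = 0) {
  if (base_radius < 3) .stopf("flowseg_invalid_spec", "base_radius must be >= 3")
  if (boundary_wobble_amplitude < 0 || boundary_wobble_amplitude >= 1)
    .stopf("flowseg_invalid_spec",
           "boundary_wobble_amplitude must be in [0, 1) so the boundary never self-intersects")
  if (texture_length_scale <= 0)
    .stopf("flowseg_invalid_spec", "texture_length_scale must be positive")
  structure(list(initial_centroid = as.numeric(initial_centroid),
                 base_radius = base_radius,
                 velocity = as.numeric(velocity),
                 boundary_wobble_amplitude = boundary_wobble_amplitude,
                 boundary_wobble_rate = boundary_wobble_rate,
                 interior_texture_contrast = interior_texture_contrast,
                 texture_length_scale = texture_length_scale,
                 texture_flicker_rate = texture_flicker_rate),
            class = "cell_spec")
}

#' Specification of a synthetic time-lapse scene
#'
#' Describes a full scene: canvas, cells, one of two static backgrounds —
#' `"flat"` (uniform) or `"stripes"` (a high-contrast square-wave groove
#' pattern whose intensities overlap the cells') — plus per-frame additive
#' Gaussian sensor noise. The background's noiseless component is
#' regenerated identically each frame: only the cells (and the noise) move.
#'
#' @param height,width Canvas size in pixels (>= 16 each).
#' @param n_frames Number of frames (>= 2).
#' @param cells List of [cell_spec()]s; every cell must fit inside the
#'   canvas at every frame.
#' @param background `"flat"` or `"stripes"`.
#' @param background_noise_sigma Sd of the per-frame additive Gaussian
#'   sensor noise, on the \[0,1\] intensity scale.
#' @param background_texture_contrast,background_texture_length Amplitude
#'   and correlation length (pixels) of a weak *static* spatial texture
#'   added to either background, emulating the substrate/illumination
#'   structure present in real detector images. Flow needs this static
#'   structure as an anchor: a featureless background under pure
#'   frame-to-frame sensor noise has no stable displacement at all.
#' @param stripe_period,stripe_contrast Period (pixels) and half-amplitude
#'   of the stripe pattern (stripes mode only).
#' @param rng_seed Integer seed; identical seeds give bit-identical scenes.
#' @param calibrated_th Optional flow threshold recorded for this scene
#'   (used by the presets; see [preset_scenes()]).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(height, width, n_frames, cells,
                       background = c("flat", "stripes"),
                       background_noise_sigma = 0.01,
                       background_texture_contrast = 0.04,
                       background_texture_length = 4,
                       stripe_period = 12, stripe_contrast = 0.25,
                       rng_seed = 1L, calibrated_th = NULL) {
  background <- match.arg(background)
  if (height < 16 || width < 16)
    .stopf("flowseg_invalid_spec", "canvas must be at least 16x16")
  if (n_frames < 2) .stopf("flowseg_invalid_spec", "n_frames must be >= 2")
  if (background_noise_sigma < 0)
    .stopf("flowseg_invalid_spec", "background_noise_sigma must be >= 0")
  cells <- lapply(cells, function(cl) {
    if (!inherits(cl, "cell_spec"))
      .stopf("flowseg_invalid_spec", "cells must be cell_specs")
    cl
  })
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    rmax <- cl$base_radius * (1 + cl$boundary_wobble_amplitude)
    for (t in seq_len(n_frames) - 1L) {
      ctr <- cl$initial_centroid + t * cl$velocity
      if (ctr[1] - rmax < 1 || ctr[1] + rmax > height - 2 ||
          ctr[2] - rmax < 1 || ctr[2] + rmax > width - 2)
        .stopf("flowseg_invalid_spec",
               "cell %d leaves the canvas at frame %d", i, t)
    }
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames), cells = cells,
                 background = background,
                 background_noise_sigma = background_noise_sigma,
                 background_texture_contrast = background_texture_contrast,
                 background_texture_length = background_texture_length,
                 stripe_period = stripe_period,
                 stripe_contrast = stripe_contrast,
                 rng_seed = as.integer(rng_seed),
                 calibrated_th = calibrated_th),
            class = "scene_spec")
}

# Bilinear sample of matrix `x` at fractional (rcoord, ccoord), clamped.
.sample_bilinear <- function(x, rcoord, ccoord) {
  h <- nrow(x); w <- ncol(x)
  rcoord <- pmin(pmax(rcoord, 1), h)
  ccoord <- pmin(pmax(ccoord, 1), w)
  r0 <- pmin.int(floor(rcoord), h - 1L); c0 <- pmin.int(floor(ccoord), w - 1L)
  ar <- rcoord - r0; ac <- ccoord - c0
  i00 <- (c0 - 1L) * h + r0
  x[i00] * (1 - ar) * (1 - ac) + x[i00 + 1L] * ar * (1 - ac) +
    x[i00 + h] * (1 - ar) * ac + x[i00 + h + 1L] * ar * ac
}

# Smoothed, standardized noise field of side s.
.texture_field <- function(s, length_scale) {
  x <- matrix(stats::rnorm(s * s), s, s)
  x <- .correlate_sep(x, .gaussian_kernel(length_scale),
                      .gaussian_kernel(length_scale), boundary = "mirror")
  (x - mean(x)) / stats::sd(x)
}

# Static (frame-invariant) background: base level, optional stripe pattern,
# and a weak static texture that anchors the background flow near zero.
# Draws from the current RNG stream; called once per scene inside with_seed().
.static_background <- function(spec) {
  base <- matrix(0.45, spec$height, spec$width)
  if (spec$background == "stripes") {
    stripe <- sign(sin(2 * pi * (seq_len(spec$width) - 1) / spec$stripe_period))
    stripe[stripe == 0] <- 1
    base <- base + spec$stripe_contrast *
      matrix(stripe, spec$height, spec$width, byrow = TRUE)
  }
  if (spec$background_texture_contrast > 0) {
    k <- .gaussian_kernel(spec$background_texture_length)
    tex <- matrix(stats::rnorm(spec$height * spec$width),
                  spec$height, spec$width)
    tex <- .correlate_sep(tex, k, k, boundary = "mirror")
    tex <- (tex - mean(tex)) / stats::sd(tex)
    base <- base + spec$background_texture_contrast * tex
  }
  base
}

#' Render a synthetic scene into frames plus ground truth
#'
#' Produces the image sequence and, for every frame, the exact rasterized
#' ground-truth mask of each cell. All randomness (boundary modes, texture
#' fields, sensor noise) derives from `spec$rng_seed`; the caller's RNG
#' state is left untouched.
#'
#' @param spec A [scene_spec()].
#' @return List with `sequence` (an [image_sequence()]) and `truth`
#'   (list of [labeled_mask()]s, one per frame).
#' @examples
#' sc <- preset_scenes()$single_migrating
#' out <- render_scene(sc)
#' out$sequence
#' @export
render_scene <- function(spec) {
  if (!inherits(spec, "scene_spec"))
    .stopf("flowseg_invalid_spec", "spec must be a scene_spec")
  withr::with_seed(spec$rng_seed, {
    h <- spec$height; w <- spec$width
    bg <- .static_background(spec)
    rows <- matrix(seq_len(h) - 1, h, w)          # 0-based coordinates
    cols <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)

    cells <- lapply(spec$cells, function(cl) {
      modes <- 2:4
      cm <- stats::runif(length(modes), 0.2, 1)
      cm <- cm / sum(cm)
      phases <- stats::runif(length(modes), 0, 2 * pi)
      s <- 2L * (ceiling(cl$base_radius * (1 + cl$boundary_wobble_amplitude)) + 3L) + 1L
      list(spec = cl, modes = modes, cm = cm, phases = phases,
           tex_a = .texture_field(s, cl$texture_length_scale),
           tex_b = .texture_field(s, cl$texture_length_scale),
           tex_half = (s + 1) / 2)
    })

    frames <- vector("list", spec$n_frames)
    truths <- vector("list", spec$n_frames)
    for (t in seq_len(spec$n_frames) - 1L) {
      img <- bg
      lab <- matrix(0L, h, w)
      for (i in seq_along(cells)) {
        cc <- cells[[i]]; cl <- cc$spec
        ctr <- cl$initial_centroid + t * cl$velocity
        dr <- rows - ctr[1]; dc <- cols - ctr[2]
        dist <- sqrt(dr^2 + dc^2)
        theta <- atan2(dr, dc)
        rad <- cl$base_radius * (1 + cl$boundary_wobble_amplitude *
          Reduce(`+`, lapply(seq_along(cc$modes), function(k)
            cc$cm[k] * cos(cc$modes[k] * theta + cc$phases[k] +
                           cl$boundary_wobble_rate * t))))
        inside <- dist <= rad
        if (cl$interior_texture_contrast > 0) {
          ph <- 2 * pi * cl$texture_flicker_rate * t
          tex <- cos(ph) * .sample_bilinear(cc$tex_a, dr[inside] + cc$tex_half,
                                            dc[inside] + cc$tex_half) +
                 sin(ph) * .sample_bilinear(cc$tex_b, dr[inside] + cc$tex_half,
                                            dc[inside] + cc$tex_half)
          img[inside] <- 0.5 + cl$interior_texture_contrast * tex
        } else {
          img[inside] <- 0.5
        }
        lab[inside] <- i
      }
      if (spec$background_noise_sigma > 0)
        img <- img + matrix(stats::rnorm(h * w, 0, spec$background_noise_sigma), h, w)
      img[img < 0] <- 0; img[img > 1] <- 1
      frames[[t + 1L]] <- image_frame(img, t)
      truths[[t + 1L]] <- labeled_mask(lab, t)
    }
    list(sequence = image_sequence(frames), truth = truths)
  })
}

#' Frozen synthetic scene presets
#'
#' Four seeded scenes covering the conditions the pipeline must handle,
#' each carrying a recorded flow threshold (`calibrated_th`) found once by
#' a grid search maximizing pooled Jaccard on that preset and frozen:
#' \describe{
#'   \item{single_migrating}{one textured cell translating over a flat
#'     noisy background.}
#'   \item{multi_morphology}{three cells of differing radius, wobble and
#'     speed in one field of view.}
#'   \item{grooves}{one migrating cell atop a static high-contrast stripe
#'     pattern whose intensities overlap the cell's — the contact-guidance
#'     robustness scenario.}
#'   \item{stationary_active}{a cell with zero net velocity but strong
#'     interior intensity fluctuation, exercising segmentation of
#'     non-translating cells.}
#' }
#'
#' @return Named list of [scene_spec()]s.
#' @export
preset_scenes <- function() {
  list(
    single_migrating = scene_spec(
      height = 320, width = 320, n_frames = 6,
      cells = list(cell_spec(c(160, 150), base_radius = 100,
                             velocity = c(1.0, 2.0),
                             boundary_wobble_amplitude = 0.08,
                             boundary_wobble_rate = 0.3,
                             interior_texture_contrast = 0.18,
                             texture_length_scale = 3,
                             texture_flicker_rate = 0.10)),
      background = "flat", background_noise_sigma = 0.005,
      background_texture_contrast = 0.10,
      rng_seed = 101L, calibrated_th = 1.1),
    multi_morphology = scene_spec(
      height = 384, width = 384, n_frames = 5,
      cells = list(
        cell_spec(c(100, 100), base_radius = 60, velocity = c(1.0, 1.0),
                  boundary_wobble_amplitude = 0.06,
                  interior_texture_contrast = 0.18,
                  texture_flicker_rate = 0.10),
        cell_spec(c(110, 290), base_radius = 70, velocity = c(0.5, -1.0),
                  boundary_wobble_amplitude = 0.10,
                  boundary_wobble_rate = 0.4,
                  interior_texture_contrast = 0.15,
                  texture_flicker_rate = 0.12),
        cell_spec(c(285, 190), base_radius = 80, velocity = c(-1.0, 0.8),
                  boundary_wobble_amplitude = 0.04,
                  interior_texture_contrast = 0.20,
                  texture_length_scale = 4,
                  texture_flicker_rate = 0.08)),
      background = "flat", background_noise_sigma = 0.005,
      background_texture_contrast = 0.10,
      rng_seed = 202L, calibrated_th = 0.7),
    grooves = scene_spec(
      height = 320, width = 320, n_frames = 6,
      cells = list(cell_spec(c(160, 150), base_radius = 100,
                             velocity = c(1.5, 1.0),
                             boundary_wobble_amplitude = 0.08,
                             boundary_wobble_rate = 0.3,
                             interior_texture_contrast = 0.18,
                             texture_flicker_rate = 0.10)),
      background = "stripes", background_noise_sigma = 0.005,
      background_texture_contrast = 0.10,
      stripe_period = 24, stripe_contrast = 0.25,
      rng_seed = 303L, calibrated_th = 0.9),
    stationary_active = scene_spec(
      height = 320, width = 320, n_frames = 6,
      cells = list(cell_spec(c(160, 160), base_radius = 100,
                             velocity = c(0, 0),
                             boundary_wobble_amplitude = 0.10,
                             boundary_wobble_rate = 0.5,
                             interior_texture_contrast = 0.25,
                             texture_flicker_rate = 0.25)),
      background = "flat", background_noise_sigma = 0.005,
      background_texture_contrast = 0.10,
      rng_seed = 404L, calibrated_th = 1.1)
  )
}
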