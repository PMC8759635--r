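#' Segmentation parameters
#'
#' The method's user-facing knobs. `th` is the primary parameter: the flow
#' magnitude (pixels/frame, on \[0,1\]-normalized intensities) above which
#' a pixel is classified as cell. The two secondary machine-vision
#' parameters rarely need retuning: a smoothing disk of radius 1 and a
#' 1000-pixel size filter suit typical single-cell fields of view.
#'
#' @param th Positive flow-magnitude threshold (pixels/frame).
#' @param disk_radius Non-negative integer radius of the disk structuring
#'   element used by morphological closing; 0 disables smoothing.
#' @param min_size Non-negative minimum object area in pixels; smaller
#'   connected components (debris, precipitates) are discarded.
#' @return A `seg_params` list.
#' @export
seg_params <- function(th, disk_radius = 1L, min_size = 1000L) {
  if (!is.numeric(th) || length(th) != 1L || th <= 0)
    .stopf("flowseg_invalid_params", "th must be a positive number")
  if (disk_radius < 0) .stopf("flowseg_invalid_params", "disk_radius must be >= 0")
  if (min_size < 0) .stopf("flowseg_invalid_params", "min_size must be >= 0")
  structure(list(th = th, disk_radius = as.integer(disk_radius),
                 min_size = as.integer(min_size)),
            class = "seg_params")
}

#' Binary mask container
#'
#' @param pixels Logical matrix; `TRUE` marks cell pixels.
#' @param pair_index Time index of the earlier frame of the pair the mask
#'   was derived from (or the frame index for ground truth).
#' @return A `binary_mask`.
#' @export
binary_mask <- function(pixels, pair_index = 0L) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    .stopf("flowseg_invalid_mask", "pixels must be a logical matrix")
  structure(pixels, pair_index = as.integer(pair_index),
            class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground px, t = %d\n",
              nrow(x), ncol(x), sum(x), attr(x, "pair_index")))
  invisible(x)
}

#' Threshold the flow magnitude into a binary mask
#'
#' A pixel is cell iff its flow magnitude is strictly above `th`; pixels at
#' or below the threshold are background.
#'
#' @param magnitude Non-negative numeric matrix from [flow_magnitude()].
#' @param params A [seg_params()].
#' @param pair_index Frame-pair index propagated to the mask.
#' @return A [binary_mask()].
#' @export
threshold_mask <- function(magnitude, params, pair_index = 0L) {
  if (any(!is.finite(magnitude)))
    .stopf("flowseg_invalid_mask", "magnitude contains NaN/Inf")
  binary_mask(magnitude > params$th, pair_index)
}

# Disk structuring element offsets {(dr,dc): dr^2 + dc^2 <= r^2}
.disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Dilation/erosion on the Z^2 set definition: the mask is padded by the
# disk radius so dilation can grow past the original canvas and closing
# stays extensive at image borders.
.dilate_pad <- function(m, off, r) {
  h <- nrow(m) + 2L * r; w <- ncol(m) + 2L * r
  p <- matrix(FALSE, h, w)
  p[(r + 1L):(h - r), (r + 1L):(w - r)] <- m
  out <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(off)))
    out <- out | .shift_matrix(p, off$dr[i], off$dc[i], FALSE)
  out
}

.erode <- function(p, off) {
  out <- matrix(TRUE, nrow(p), ncol(p))
  for (i in seq_len(nrow(off)))
    out <- out & .shift_matrix(p, off$dr[i], off$dc[i], FALSE)
  out
}

# 8-connected foreground labeling. EBImage::bwlabel is 4-connected, so
# labels touching only diagonally are merged with a union-find pass.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    sh <- .shift_matrix(lab, d[1], d[2], 0L)
    pair <- lab > 0L & sh > 0L & lab != sh
    if (any(pair)) {
      pr <- unique(cbind(lab[pair], sh[pair]))
      for (k in seq_len(nrow(pr))) union(pr[k, 1], pr[k, 2])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab[lab > 0L] <- match(roots, sort(unique(roots)))[lab[lab > 0L]]
  lab
}

# Relabel 1..N in raster-scan (row-major) order of each label's first pixel.
.relabel_raster <- function(lab) {
  present <- sort(unique(lab[lab > 0L]))
  if (length(present) == 0L) return(lab)
  # row-major linear position of each label's first pixel
  pos <- (row(lab) - 1) * ncol(lab) + col(lab)
  first <- vapply(present, function(l) min(pos[lab == l]), numeric(1))
  remap <- integer(max(present))
  remap[present[order(first)]] <- seq_along(present)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Morphological closing and hole filling
#'
#' Closes the mask with a disk structuring element of radius
#' `disk_radius` (dilation then erosion on the set definition, so the
#' output always contains the input; radius 0 skips closing), then fills
#' every background region not connected to the image border. Foreground
#' is 8-connected, background 4-connected (the standard dual pairing that
#' avoids topological paradoxes in the fill).
#'
#' @param mask A [binary_mask()].
#' @param params A [seg_params()].
#' @return A [binary_mask()].
#' @export
close_and_fill <- function(mask, params) {
  m <- unclass(mask); attributes(m) <- list(dim = dim(mask))
  r <- params$disk_radius
  if (r > 0L) {
    off <- .disk_offsets(r)
    p <- .erode(.dilate_pad(m, off, r), off)
    m <- p[(r + 1L):(nrow(p) - r), (r + 1L):(ncol(p) - r), drop = FALSE]
  }
  # fill: 4-connected background components not touching the border
  bg <- EBImage::bwlabel(matrix(as.numeric(!m), nrow(m), ncol(m)))
  bg <- matrix(as.integer(bg), nrow(m), ncol(m))
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  hole <- bg > 0L & !(bg %in% border_labels)
  m[hole] <- TRUE
  binary_mask(m, attr(mask, "pair_index"))
}

#' Remove connected components smaller than the size filter
#'
#' 8-connected components with area strictly below `min_size` are removed;
#' components exactly at `min_size` survive.
#'
#' @inheritParams close_and_fill
#' @return A [binary_mask()].
#' @export
size_filter <- function(mask, params) {
  m <- unclass(mask); attributes(m) <- list(dim = dim(mask))
  if (params$min_size <= 0L || !any(m))
    return(binary_mask(m, attr(mask, "pair_index")))
  lab <- .label8(m)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= params$min_size)
  binary_mask(matrix(lab %in% keep, nrow(m), ncol(m)),
              attr(mask, "pair_index"))
}

# Region properties for an integer label image. Perimeter is the count of
# region pixels with at least one 4-neighbour outside the region (the image
# border counts as outside).
.measure_labels <- function(lab, pair_index = 0L) {
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(frame = integer(), label = integer(),
                          area_px = integer(), perimeter_px = integer(),
                          centroid_row = double(), centroid_col = double(),
                          bbox_min_row = integer(), bbox_min_col = integer(),
                          bbox_max_row = integer(), bbox_max_col = integer()))
  }
  h <- nrow(lab); w <- ncol(lab)
  boundary <- lab > 0L & (
    .shift_matrix(lab, 1L, 0L, -1L) != lab |
    .shift_matrix(lab, -1L, 0L, -1L) != lab |
    .shift_matrix(lab, 0L, 1L, -1L) != lab |
    .shift_matrix(lab, 0L, -1L, -1L) != lab)
  fg <- lab > 0L
  l <- lab[fg]; rr <- row(lab)[fg]; cc <- col(lab)[fg]; bd <- boundary[fg]
  tibble::tibble(
    frame = as.integer(pair_index),
    label = seq_len(n),
    area_px = as.integer(tabulate(l, n)),
    perimeter_px = as.integer(tabulate(l[bd], n)),
    centroid_row = as.vector(tapply(rr, l, mean)) - 1,
    centroid_col = as.vector(tapply(cc, l, mean)) - 1,
    bbox_min_row = as.vector(tapply(rr, l, min)) - 1L,
    bbox_min_col = as.vector(tapply(cc, l, min)) - 1L,
    bbox_max_row = as.vector(tapply(rr, l, max)),      # half-open
    bbox_max_col = as.vector(tapply(cc, l, max))
  )
}

#' Label a binary mask and measure its regions
#'
#' 8-connected components are labeled 1..N in raster-scan (row-major)
#' order of their first pixel, and per-region area, perimeter (count of
#' boundary pixels), centroid and half-open bounding box are tabulated.
#' Coordinates are 0-based `(row, col)`.
#'
#' @param mask A [binary_mask()].
#' @return A `labeled_mask`: list with the integer `labels` matrix
#'   (0 = background) and a `regions` tibble.
#' @export
label_and_measure <- function(mask) {
  m <- unclass(mask); attributes(m) <- list(dim = dim(mask))
  lab <- .relabel_raster(.label8(m))
  labeled_mask(lab, attr(mask, "pair_index"))
}

#' @rdname label_and_measure
#' @param labels Non-negative integer matrix of region labels
#'   (0 = background); labels need not be consecutive and are relabeled
#'   1..N in raster-scan order.
#' @param pair_index Frame index the mask belongs to.
#' @export
labeled_mask <- function(labels, pair_index = 0L) {
  if (!is.matrix(labels) || any(labels < 0) || any(!is.finite(labels)))
    .stopf("flowseg_invalid_mask", "labels must be a nonnegative integer matrix")
  lab <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  lab <- .relabel_raster(lab)
  structure(list(labels = lab,
                 regions = .measure_labels(lab, pair_index),
                 pair_index = as.integer(pair_index)),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d x %d, %d region(s), t = %d\n",
              nrow(x$labels), ncol(x$labels), max(x$labels), x$pair_index))
  if (max(x$labels) > 0L) print(x$regions)
  invisible(x)
}

#' Segment one consecutive frame pair
#'
#' The full chain: dense flow ([farneback_flow()]), magnitude, threshold at
#' `th`, morphological closing and hole filling, size filter, then region
#' labeling and measurement. The resulting mask is assigned to the earlier
#' frame's index (flow "pushes" pixels from `t` to `t+1`).
#'
#' @param frame_t,frame_t1 Consecutive [image_frame()]s.
#' @param fparams A [flow_params()].
#' @param sparams A [seg_params()].
#' @return A [labeled_mask()] for frame `t`.
#' @export
segment_pair <- function(frame_t, frame_t1, fparams = flow_params(), sparams) {
  fl <- farneback_flow(frame_t, frame_t1, fparams)
  mask <- threshold_mask(flow_magnitude(fl), sparams, fl$pair_index)
  mask <- close_and_fill(mask, sparams)
  mask <- size_filter(mask, sparams)
  label_and_measure(mask)
}

#' Segment a whole time-lapse sequence pairwise
#'
#' Applies [segment_pair()] to every consecutive pair of an
#' [image_sequence()]: N frames yield N-1 labeled masks, each assigned to
#' the earlier frame of its pair. Use [regions()] to pool the per-frame
#' region tables for downstream morphology/migration analysis.
#'
#' @param seq An [image_sequence()].
#' @inheritParams segment_pair
#' @return List of [labeled_mask()]s, one per frame pair.
#' @export
segment_sequence <- function(seq, fparams = flow_params(), sparams) {
  if (!inherits(seq, "image_sequence"))
    .stopf("flowseg_invalid_sequence", "seq must be an image_sequence")
  n <- length(seq$frames)
  lapply(seq_len(n - 1L), function(i)
    segment_pair(seq$frames[[i]], seq$frames[[i + 1L]], fparams, sparams))
}

#' Pooled region table of a segmentation result
#'
#' @param masks A `labeled_mask` or list of them.
#' @return A tibble with one row per region, columns
#'   `frame, label, area_px, perimeter_px, centroid_row, centroid_col,
#'   bbox_min_row, bbox_min_col, bbox_max_row, bbox_max_col`
#'   (0-based coordinates, half-open boxes).
#' @export
regions <- function(masks) {
  if (inherits(masks, "labeled_mask")) masks <- list(masks)
  dplyr::bind_rows(lapply(masks, function(m) m$regions))
}
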