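#' Read a time-lapse sequence from disk
#'
#' Accepts either a multi-page TIFF or a directory of single-image TIFF or
#' PNG frames ordered lexicographically by filename. Integer TIFF data are
#' normalized by their recorded bit depth ([normalize_frame()]);
#' floating-point TIFF data are min-max rescaled; PNG data arrive from the
#' decoder already on \[0, 1\] and are taken as-is. Multi-channel frames
#' are converted to luminance (Rec. 709 weights) with a warning.
#'
#' @param path A multi-page TIFF file or a directory of TIFF/PNG frames.
#' @param frame_interval Seconds between frames (metadata).
#' @return An [image_sequence()] with frame indices 0, 1, 2, ...
#' @export
read_sequence <- function(path, frame_interval = 1) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L)
      .stopf("flowseg_invalid_sequence",
             "found %d frame(s) in %s; the method is defined on consecutive pairs (need >= 2)",
             length(files), path)
    frames <- lapply(seq_along(files), function(i)
      .read_one_frame(files[i], i - 1L))
  } else if (file.exists(path)) {
    if (!grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
      .stopf("flowseg_invalid_sequence",
             "%s: single-file input must be a multi-page TIFF", path)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(pages) < 2L)
      .stopf("flowseg_invalid_sequence",
             "%s has %d page(s); the method is defined on consecutive pairs (need >= 2)",
             path, length(pages))
    frames <- lapply(seq_along(pages), function(i)
      .frame_from_array(pages[[i]], i - 1L, sprintf("%s page %d", path, i)))
  } else {
    .stopf("flowseg_invalid_sequence", "path %s does not exist", path)
  }
  d1 <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d1))
      .stopf("flowseg_invalid_sequence",
             "frame %d has dimensions %dx%d, expected %dx%d",
             i - 1L, nrow(frames[[i]]), ncol(frames[[i]]), d1[1], d1[2])
  }
  image_sequence(frames, frame_interval)
}

.read_one_frame <- function(file, index) {
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    a <- png::readPNG(file)           # already scaled to [0, 1]
    a <- .to_luminance(a, file)
    image_frame(a, index, "float")
  } else {
    a <- tiff::readTIFF(file, as.is = TRUE)
    .frame_from_array(a, index, file)
  }
}

.frame_from_array <- function(a, index, what) {
  a <- .to_luminance(a, what)
  if (is.integer(a) || (is.numeric(a) && !is.null(attr(a, "bits.per.sample")) &&
                        max(a) > 1)) {
    bits <- attr(a, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(a) > 255) 16L else 8L
    m <- matrix(as.numeric(a), nrow(a), ncol(a))
    normalize_frame(m, as.integer(bits), index)
  } else {
    m <- matrix(as.numeric(a), nrow(a), ncol(a))
    if (min(m) >= 0 && max(m) <= 1) image_frame(m, index, "float")
    else normalize_frame(m, "float", index)
  }
}

.to_luminance <- function(a, what) {
  if (length(dim(a)) == 3L) {
    warning(sprintf("%s is multi-channel; converting to luminance", what),
            call. = FALSE)
    wts <- c(0.2126, 0.7152, 0.0722, 0)[seq_len(dim(a)[3])]
    wts <- wts / sum(wts)
    b <- matrix(0, dim(a)[1], dim(a)[2])
    for (k in seq_len(dim(a)[3])) b <- b + wts[k] * a[, , k]
    attr(b, "bits.per.sample") <- attr(a, "bits.per.sample")
    b
  } else a
}

#' Write segmentation outputs to a directory
#'
#' Writes one 16-bit label TIFF per mask (`mask_%04d.tif`, numbered by the
#' mask's frame index, label values stored directly as 16-bit integers), a
#' pooled `regions.csv`, the effective parameters as `params.yaml`, and a
#' `manifest.json` listing every artifact.
#'
#' @param masks List of [labeled_mask()]s.
#' @param outdir Output directory (created if absent).
#' @param fparams,sparams Optional [flow_params()] / [seg_params()] echoed
#'   to `params.yaml`.
#' @return Invisibly, a tibble manifest of the files written.
#' @export
write_outputs <- function(masks, outdir, fparams = NULL, sparams = NULL) {
  if (inherits(masks, "labeled_mask")) masks <- list(masks)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir))
    .stopf("flowseg_io_error", "cannot create output directory %s", outdir)
  files <- character(0)
  for (m in masks) {
    if (max(m$labels) > 65535L)
      .stopf("flowseg_io_error", "more than 65535 labels in one mask")
    f <- file.path(outdir, sprintf("mask_%04d.tif", m$pair_index))
    tiff::writeTIFF(m$labels / 65535, f, bits.per.sample = 16L,
                    compression = "none")
    files <- c(files, f)
  }
  csv <- file.path(outdir, "regions.csv")
  utils::write.csv(regions(masks), csv, row.names = FALSE)
  files <- c(files, csv)
  yml <- file.path(outdir, "params.yaml")
  yaml::write_yaml(list(flow = if (is.null(fparams)) NULL else unclass(fparams),
                        segment = if (is.null(sparams)) NULL else unclass(sparams)),
                   yml)
  files <- c(files, yml)
  manifest <- tibble::tibble(file = basename(files),
                             bytes = file.size(files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a label mask written by [write_outputs()]
#'
#' @param file A 16-bit label TIFF (or PNG) with 0 = background.
#' @param pair_index Frame index to record on the mask; defaults to the
#'   number parsed from a `mask_%04d` filename, else 0.
#' @return A [labeled_mask()].
#' @export
read_label_mask <- function(file, pair_index = NULL) {
  if (is.null(pair_index)) {
    m <- regmatches(basename(file), regexpr("[0-9]+", basename(file)))
    pair_index <- if (length(m)) as.integer(m) else 0L
  }
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    a <- png::readPNG(file)
    lab <- round(a * 65535)
  } else {
    a <- tiff::readTIFF(file, as.is = TRUE)
    lab <- a
  }
  if (length(dim(lab)) == 3L) lab <- lab[, , 1]
  labeled_mask(matrix(as.integer(round(lab)), nrow(lab), ncol(lab)), pair_index)
}

#' Run configuration
#'
#' Assembles the effective parameter set from package defaults, an
#' optional YAML config file (keys `flow:`, `segment:`, `eval:`) and
#' explicit overrides, in that order of increasing precedence. The
#' configuration round-trips: writing and re-reading yields an identical
#' object.
#'
#' @param config_file Optional YAML file.
#' @param overrides Named list of overrides, e.g.
#'   `list(segment = list(th = 0.05))`.
#' @return A `run_config` list with `flow` ([flow_params()]), `segment`
#'   (a [seg_params()] if `th` is set, else the defaults without `th`) and
#'   `eval` (list with `iou_match_threshold`).
#' @export
run_config <- function(config_file = NULL, overrides = list()) {
  cfg <- list(flow = unclass(flow_params()),
              segment = list(th = NULL, disk_radius = 1L, min_size = 1000L),
              eval = list(iou_match_threshold = 0.5))
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      .stopf("flowseg_io_error", "config file %s not found", config_file)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(config_file))
  }
  cfg <- utils::modifyList(cfg, overrides)
  cfg$flow <- do.call(flow_params, cfg$flow[names(cfg$flow) %in%
                                              names(formals(flow_params))])
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param file Destination YAML path.
#' @export
write_config <- function(cfg, file) {
  yaml::write_yaml(list(flow = unclass(cfg$flow),
                        segment = cfg$segment, eval = cfg$eval), file)
  invisible(file)
}
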