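test_that("thresholding is strict and counts pixels exactly", {
  p <- seg_params(0.05)
  expect_false(any(threshold_mask(matrix(0, 10, 10), p)))
  mag <- matrix(0, 10, 10); mag[c(3, 17, 44, 81, 99)] <- 0.1
  expect_equal(sum(threshold_mask(mag, p)), 5L)
  expect_false(any(threshold_mask(matrix(0.05, 4, 4), p)))  # equality is background
})

test_that("closing leaves solid convex shapes unchanged and bridges gaps", {
  sq <- matrix(FALSE, 30, 30); sq[6:25, 6:25] <- TRUE
  for (r in c(1, 3, 5))
    expect_equal(unclass(close_and_fill(binary_mask(sq), seg_params(1, r)))[, ],
                 sq, ignore_attr = TRUE)
  # two bars one column apart are joined by radius-1 closing (oracle check);
  # note two isolated pixels would NOT bridge: the radius-1 Euclidean disk
  # is a cross, and erosion removes the lone bridging pixel again
  g <- matrix(FALSE, 9, 9); g[3:7, 4] <- TRUE; g[3:7, 6] <- TRUE
  got <- close_and_fill(binary_mask(g), seg_params(1, 1))
  expect_true(all(got[4:6, 5]))
  expect_equal(unclass(got)[, ], bf_fill(bf_closing(g, 1)), ignore_attr = TRUE)
  px <- matrix(FALSE, 9, 9); px[5, 4] <- TRUE; px[5, 6] <- TRUE
  gotpx <- close_and_fill(binary_mask(px), seg_params(1, 1))
  expect_equal(unclass(gotpx)[, ], bf_fill(bf_closing(px, 1)), ignore_attr = TRUE)
})

test_that("a closed ring is filled to the solid disk", {
  n <- 25; ctr <- 13
  dd <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  ring <- dd >= 9 & dd <= 10
  got <- close_and_fill(binary_mask(ring), seg_params(1, 0))
  expect_equal(unclass(got)[, ], bf_fill(ring), ignore_attr = TRUE)
  expect_equal(sum(got), sum(bf_fill(ring)))
  expect_true(all(got[dd <= 9]))
})

test_that("closing and filling never remove pixels and the fill is idempotent", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(runif(400) < 0.3, 20, 20)
    out <- close_and_fill(binary_mask(m), seg_params(1, 1))
    expect_true(all(out[m]))                       # extensive
    again <- close_and_fill(binary_mask(unclass(out)[, ] == TRUE),
                            seg_params(1, 0))      # fill step alone
    expect_equal(unclass(again)[, ], unclass(out)[, ])
  }
})

test_that("the size filter keeps components at the limit and drops smaller", {
  m <- matrix(FALSE, 60, 60)
  m[2:38, 2:28] <- TRUE            # 37 x 27 = 999
  m[41:60, 11:60] <- TRUE          # 20 x 50 = 1000
  out <- size_filter(binary_mask(m), seg_params(1, min_size = 1000))
  expect_false(any(out[2:38, 2:28]))
  expect_true(all(out[41:60, 11:60]))
  expect_equal(unclass(size_filter(binary_mask(m), seg_params(1, min_size = 0)))[, ],
               m, ignore_attr = TRUE)
  empty <- binary_mask(matrix(FALSE, 5, 5))
  expect_false(any(size_filter(empty, seg_params(1))))
})

test_that("labeling is 8-connected, raster-ordered, and measures regions", {
  lm <- label_and_measure(binary_mask(matrix(FALSE, 6, 6)))
  expect_equal(nrow(lm$regions), 0L)

  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE; m[8:10, 7:9] <- TRUE
  lm <- label_and_measure(binary_mask(m))
  expect_equal(nrow(lm$regions), 2L)
  expect_equal(lm$regions$area_px, c(9L, 9L))
  expect_equal(lm$regions$centroid_row, c(2, 8))   # 0-based centres
  expect_equal(lm$regions$centroid_col, c(2, 7))
  expect_equal(lm$regions$perimeter_px, c(8L, 8L))
  expect_equal(unname(unlist(lm$regions[1, c("bbox_min_row", "bbox_min_col",
                                             "bbox_max_row", "bbox_max_col")])),
               c(1, 1, 4, 4))

  one <- matrix(FALSE, 5, 5); one[3, 4] <- TRUE
  lm1 <- label_and_measure(binary_mask(one))
  expect_equal(lm1$regions$area_px, 1L)
  expect_equal(c(lm1$regions$centroid_row, lm1$regions$centroid_col), c(2, 3))

  # diagonal contact joins regions (8-connectivity)
  dg <- matrix(FALSE, 6, 6); dg[2, 2] <- TRUE; dg[3, 3] <- TRUE; dg[4, 4] <- TRUE
  expect_equal(max(label_and_measure(binary_mask(dg))$labels), 1L)

  # raster-scan ordering: first-encountered pixel (row-major) gets label 1
  rs <- matrix(FALSE, 6, 6); rs[5, 1] <- TRUE; rs[1, 5] <- TRUE
  lmr <- label_and_measure(binary_mask(rs))
  expect_equal(lmr$labels[1, 5], 1L)
  expect_equal(lmr$labels[5, 1], 2L)
})

test_that("identical frames segment to zero regions", {
  f <- as_frame(mk_smooth_texture(64, 13))
  lm <- segment_pair(f, as_frame(unclass(f)[, ], 1), sparams = seg_params(0.1))
  expect_equal(nrow(lm$regions), 0L)
})

test_that("a moving textured disk is segmented as one region over either background", {
  fx <- disk_pair_fixture(seed = 7, radius = 20, shift = c(0, 1.5))
  lm <- segment_pair(fx$f1, fx$f2, sparams = seg_params(0.7, min_size = 500))
  expect_equal(nrow(lm$regions), 1L)
  expect_gt(jaccard_index(binary_mask(fx$disk), binary_mask(lm$labels > 0)), 0.5)

  # same cell over a static high-contrast stripe background
  sc <- scene_spec(128, 128, 2,
                   cells = list(cell_spec(c(64, 60), base_radius = 20,
                                          velocity = c(0, 1.5),
                                          boundary_wobble_amplitude = 0,
                                          interior_texture_contrast = 0.18)),
                   background = "stripes", background_noise_sigma = 0.005,
                   background_texture_contrast = 0.10,
                   stripe_period = 16, stripe_contrast = 0.25, rng_seed = 7)
  out <- render_scene(sc)
  lm2 <- segment_pair(out$sequence$frames[[1]], out$sequence$frames[[2]],
                      sparams = seg_params(0.7, min_size = 500))
  expect_equal(nrow(lm2$regions), 1L)
  truth <- out$truth[[1]]$labels > 0
  expect_gt(sum(lm2$labels > 0 & truth) / sum(truth), 0.5)
})

test_that("sequences segment pairwise with earlier-frame mask assignment", {
  f <- lapply(0:2, function(i) as_frame(mk_smooth_texture(64, 50 + 0 * i), i))
  s <- image_sequence(f)
  masks <- segment_sequence(s, sparams = seg_params(0.1))
  expect_length(masks, 2L)
  expect_equal(vapply(masks, function(m) m$pair_index, integer(1)), c(0L, 1L))
  expect_true(all(vapply(masks, function(m) nrow(m$regions) == 0L, logical(1))))
})

test_that("mask area is non-increasing in th", {
  fx <- disk_pair_fixture(seed = 8)
  mag <- flow_magnitude(farneback_flow(fx$f1, fx$f2))
  ths <- seq(0.05, 1.4, length.out = 10)
  areas <- vapply(ths, function(th) sum(threshold_mask(mag, seg_params(th))),
                  integer(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("the segmentation pipeline is deterministic", {
  fx <- disk_pair_fixture(seed = 9)
  a <- segment_pair(fx$f1, fx$f2, sparams = seg_params(0.7, min_size = 500))
  b <- segment_pair(fx$f1, fx$f2, sparams = seg_params(0.7, min_size = 500))
  expect_identical(a$labels, b$labels)
  expect_identical(a$regions, b$regions)
})
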