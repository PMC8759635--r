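small_scene <- function(...) {
  args <- list(...)
  defaults <- list(height = 64, width = 64, n_frames = 3,
                   cells = list(cell_spec(c(32, 30), base_radius = 10,
                                          velocity = c(1, 2),
                                          boundary_wobble_amplitude = 0,
                                          interior_texture_contrast = 0.15)),
                   background = "flat", rng_seed = 5L)
  defaults[names(args)] <- args
  do.call(scene_spec, defaults)
}

test_that("identical seeds render bit-identical scenes", {
  a <- render_scene(small_scene())
  b <- render_scene(small_scene())
  for (i in 1:3) {
    expect_identical(unclass(a$sequence$frames[[i]])[, ],
                     unclass(b$sequence$frames[[i]])[, ])
    expect_identical(a$truth[[i]]$labels, b$truth[[i]]$labels)
  }
  c <- render_scene(small_scene(rng_seed = 6L))
  expect_false(identical(unclass(a$sequence$frames[[1]])[, ],
                         unclass(c$sequence$frames[[1]])[, ]))
})

test_that("rendering leaves the caller's RNG state untouched", {
  set.seed(99); before <- .Random.seed
  render_scene(small_scene())
  expect_identical(.Random.seed, before)
})

test_that("truth centroids advance exactly with an integer velocity", {
  out <- render_scene(small_scene(n_frames = 5, cells = list(
    cell_spec(c(30, 25), base_radius = 10, velocity = c(2, 0),
              boundary_wobble_amplitude = 0, interior_texture_contrast = 0.15))))
  cent <- t(vapply(out$truth, function(tm)
    c(tm$regions$centroid_row, tm$regions$centroid_col), numeric(2)))
  expect_equal(diff(cent[, 1]), rep(2, 4))
  expect_equal(diff(cent[, 2]), rep(0, 4))
})

test_that("a fully static specification renders identical frames with zero flow", {
  out <- render_scene(small_scene(
    cells = list(cell_spec(c(32, 32), base_radius = 10, velocity = c(0, 0),
                           boundary_wobble_amplitude = 0,
                           interior_texture_contrast = 0)),
    background_noise_sigma = 0))
  f <- out$sequence$frames
  expect_identical(unclass(f[[1]])[, ], unclass(f[[2]])[, ])
  fl <- farneback_flow(f[[1]], f[[2]])
  expect_lt(max(flow_magnitude(fl)), 1e-6)
})

test_that("a cell-free stripe scene is static and segments to empty masks", {
  out <- render_scene(small_scene(cells = list(), background = "stripes",
                                  background_noise_sigma = 0))
  f <- out$sequence$frames
  expect_identical(unclass(f[[1]])[, ], unclass(f[[3]])[, ])
  masks <- segment_sequence(out$sequence, sparams = seg_params(0.1))
  expect_true(all(vapply(masks, function(m) nrow(m$regions) == 0L, logical(1))))
})

test_that("truth mask area stays within the wobble bound across frames", {
  amp <- 0.05; r <- 12
  out <- render_scene(small_scene(n_frames = 6, cells = list(
    cell_spec(c(32, 32), base_radius = r, velocity = c(0, 0),
              boundary_wobble_amplitude = amp, boundary_wobble_rate = 0.7,
              interior_texture_contrast = 0.15))))
  areas <- vapply(out$truth, function(tm) tm$regions$area_px, integer(1))
  expect_lt(max(areas) - min(areas), 2 * amp * pi * r^2)
})

test_that("cells that would leave the canvas are rejected at validation", {
  expect_error(small_scene(cells = list(
    cell_spec(c(32, 55), base_radius = 10, velocity = c(0, 3)))),
    class = "flowseg_invalid_spec")
})

test_that("presets are fixed, deterministic, and carry their conditions", {
  p1 <- preset_scenes(); p2 <- preset_scenes()
  expect_identical(p1, p2)
  expect_setequal(names(p1), c("single_migrating", "multi_morphology",
                               "grooves", "stationary_active"))
  expect_equal(p1$grooves$background, "stripes")
  expect_equal(p1$stationary_active$cells[[1]]$velocity, c(0, 0))
  for (p in p1) expect_true(is.numeric(p$calibrated_th) && p$calibrated_th > 0)
})
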