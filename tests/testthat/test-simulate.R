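test_that("a static configuration renders a static scene", {
  g <- static_scene()
  tr <- g$truth
  expect_equal(length(unique(tr$x_px)), 1L)
  expect_equal(length(unique(tr$y_px)), 1L)
  # rendered disk centroid drifts < 0.5 px across frames
  cents <- vapply(seq_len(5), function(t) {
    f <- g$video[, , t]
    idx <- which(f < 0.6, arr.ind = TRUE)
    c(mean(idx[, 2] - 1), mean(idx[, 1] - 1))
  }, numeric(2))
  expect_lt(max(abs(cents[1, ] - tr$x_px[1])), 0.5)
  expect_lt(max(abs(cents[2, ] - tr$y_px[1])), 0.5)
})

test_that("the same seed reproduces video and truth bit-identically", {
  cfg <- simulation_config(image_size = c(256L, 256L), n_frames = 8L,
                           n_clusters = 2L, cells_per_cluster = 3L,
                           inter_cluster_spacing = 40, seed = 9L)
  a <- generate_video(cfg)
  b <- generate_video(cfg)
  expect_identical(unclass(a$video), unclass(b$video))
  expect_identical(a$truth, b$truth)
})

test_that("fluctuation amplitude drives the per-track area dynamics", {
  sds <- lapply(1:2, function(cls) {
    cfg <- simulation_config(
      image_size = c(480L, 480L), n_frames = 30L, n_clusters = 4L,
      cells_per_cluster = 5L,
      class_params = list(list(fluctuation_amplitude = 0),
                          list(fluctuation_amplitude = 0.3)),
      seed = 100L + cls)
    g <- generate_video(cfg, class_of_video = cls)
    vapply(split(g$truth$area_px2, g$truth$cell_id), sd, numeric(1))
  })
  expect_equal(length(sds[[1]]), 20L)
  d <- (mean(sds[[2]]) - mean(sds[[1]])) /
    sqrt((var(sds[[1]]) + var(sds[[2]])) / 2)
  expect_gt(d, 1)
})

test_that("video values stay in range and cells are darker than background", {
  g <- static_scene()
  expect_gte(min(g$video), 0)
  expect_lte(max(g$video), 1)
  centre <- g$video[round(g$truth$y_px[1]) + 1, round(g$truth$x_px[1]) + 1, 1]
  expect_lt(centre, 0.75 - 0.2)
})

test_that("impossible cluster layouts fail explicitly", {
  expect_error(
    generate_video(simulation_config(image_size = c(256L, 256L),
                                     n_clusters = 12L,
                                     inter_cluster_spacing = 100,
                                     seed = 1L)),
    "density too high")
  expect_error(simulation_config(background_level = 0.99, noise_sd = 0.02),
               "noise_sd")
  expect_error(simulation_config(resolution = -1))
})

test_that("bias injection is additive, clamped on request, and recorded", {
  x <- frame_stack(matrix(c(0.2, 0.5, 0.7, 0.9), 2, 2))
  expect_identical(unclass(inject_bias(x, 0))[, , 1], unclass(x)[, , 1])
  expect_equal(unclass(inject_bias(x, 0.3))[2, 1, 1], 0.8)
  expect_equal(unclass(inject_bias(x, 0.5, clip = TRUE))[1, 2, 1], 1.0)
  # composition without clipping
  a <- inject_bias(inject_bias(x, 0.1), 0.15)
  b <- inject_bias(x, 0.25)
  expect_equal(as.vector(unclass(a)), as.vector(unclass(b)))
  expect_equal(attr(a, "bias"), 0.25)
})

test_that("video TIFF round-trip preserves the pixel data", {
  g <- static_scene()
  path <- withr::local_tempfile(fileext = ".tif")
  write_video_tiff(g$video, path)
  back <- read_video_tiff(path)
  expect_equal(dim(back), dim(g$video))
  expect_lt(max(abs(unclass(back) - unclass(g$video))), 1e-6)
})
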