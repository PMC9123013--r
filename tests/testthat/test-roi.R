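test_that("an interior crop equals the corresponding sub-array", {
  g <- static_scene()
  tr <- data.frame(frame = 1:5, x = g$truth$x_px, y = g$truth$y_px)
  roi <- extract_roi_sequence(g$video, tr)
  expect_equal(dim(unclass(roi)), c(63, 63, 5))
  cx <- round(tr$x[1]) + 1; cy <- round(tr$y[1]) + 1
  expect_identical(unclass(roi)[, , 1],
                   unclass(g$video)[(cy - 31):(cy + 31), (cx - 31):(cx + 31), 1])
  expect_equal(attr(roi, "stage"), "raw")
})

test_that("edge-adjacent crops are replicate-padded", {
  g <- static_scene()
  tr <- data.frame(frame = 1, x = 5, y = 5)
  roi <- extract_roi_sequence(g$video, tr)
  arr <- unclass(roi)
  expect_equal(dim(arr), c(63, 63, 1))
  # the out-of-frame corner replicates the frame's first row/column
  expect_true(all(arr[1:26, 1, 1] == arr[27, 1, 1]))
  expect_true(all(arr[1, 1:26, 1] == arr[1, 27, 1]))
})

test_that("inversion is the linear map 1 - I", {
  roi <- random_roi()
  inv <- invert_roi(roi)
  expect_equal(max(abs((1 - unclass(roi)) - unclass(inv))), 0)
  expect_equal(attr(inv, "stage"), "inverted")
  expect_equal(mean(unclass(inv)), 1 - mean(unclass(roi)))
  # involution via a fresh raw wrap
  back <- invert_roi(morphodyn:::advance_stage(inv, unclass(inv), "raw"))
  expect_equal(as.vector(unclass(back)), as.vector(unclass(roi)))
})

test_that("background suppression matches the piecewise map", {
  # equal-area graylevels {0.2, 0.4, 0.6, 0.8}: mean 0.5 -> {0, 0, 0.1, 0.3}
  vals <- rep(c(0.2, 0.4, 0.6, 0.8), length.out = 63 * 63)
  # 63*63 is one more than a multiple of 4; set the odd pixel to 0.5 so the
  # frame mean is exactly 0.5
  vals[3969] <- 0.5
  arr <- array(vals, dim = c(63, 63, 1))
  m <- mean(arr[, , 1])
  roi <- morphodyn:::new_roi_sequence(arr, "inverted", 1L, 1L)
  out <- unclass(suppress_background(roi, preprocess_config(quantization = 0)))
  expect_equal(sort(unique(round(as.vector(out), 10))),
               sort(unique(round(pmax(c(0.2, 0.4, 0.6, 0.8, 0.5) - m, 0), 10))))
  # uniform frame maps to all zeros
  u <- morphodyn:::new_roi_sequence(array(0.4, c(63, 63, 1)), "inverted", 1L, 1L)
  expect_true(all(unclass(suppress_background(u)) == 0))
})

test_that("suppression is exactly invariant to a constant offset", {
  set.seed(21)
  for (rep_ in 1:5) {
    arr <- array(runif(63 * 63 * 3, 0.2, 0.6), dim = c(63, 63, 3))
    a <- suppress_background(morphodyn:::new_roi_sequence(arr, "inverted", 1L, 1:3))
    b <- suppress_background(morphodyn:::new_roi_sequence(arr - 0.15, "inverted", 1L, 1:3))
    expect_identical(as.vector(unclass(a)), as.vector(unclass(b)))
  }
})

test_that("the Gaussian window has peak 1 and the closed-form falloff", {
  w <- morphodyn:::gaussian_window_matrix(63, 18)
  expect_equal(w[32, 32], 1)
  expect_equal(w[32, 32 + 18], exp(-1 / 2))
  expect_equal(w[32 + 18, 32], exp(-1 / 2))
  # all-zero input stays all-zero
  z <- morphodyn:::new_roi_sequence(array(0, c(63, 63, 2)), "suppressed", 1L, 1:2)
  expect_true(all(unclass(gaussian_window(z)) == 0))
})

test_that("first-frame stretch maps the quantile graylevels to 0, 1, 0.5", {
  set.seed(5)
  arr <- array(runif(63 * 63 * 1), dim = c(63, 63, 1))
  l <- quantile(arr[, , 1], c(0.01, 0.99), names = FALSE, type = 7)
  st <- morphodyn:::stretch_frame(arr[, , 1], l[1], l[2])
  i1 <- which.min(abs(arr[, , 1] - l[1]))
  expect_equal(st[i1], (arr[, , 1][i1] - l[1]) / (l[2] - l[1]))
  expect_equal(morphodyn:::stretch_frame(matrix(l[1], 2, 2), l[1], l[2])[1, 1], 0)
  expect_equal(morphodyn:::stretch_frame(matrix(l[2], 2, 2), l[1], l[2])[1, 1], 1)
  expect_equal(morphodyn:::stretch_frame(matrix(mean(l), 2, 2), l[1], l[2])[1, 1],
               0.5)
  # degenerate first frame: defined fallback, no division by zero
  deg <- morphodyn:::new_roi_sequence(array(0.3, c(63, 63, 2)), "windowed", 1L, 1:2)
  out <- enhance_sequence(deg)
  expect_true(all(is.finite(unclass(out))))
})

test_that("matching a frame to itself is the identity", {
  set.seed(6)
  raw <- array(rep(runif(63 * 63, 0.2, 0.8), 2), dim = c(63, 63, 2))
  roi <- morphodyn:::new_roi_sequence(raw, "raw", 1L, 1:2)
  e <- preprocess(roi, preprocess_config())
  expect_equal(max(abs(unclass(e)[, , 2] - unclass(e)[, , 1])), 0)
})

test_that("histogram matching brings the binned CDFs together", {
  binned_ks <- function(a, b, bins = 256) {
    br <- seq(0, 1, length.out = bins + 1)
    ca <- cumsum(tabulate(findInterval(a, br, all.inside = TRUE), bins)) / length(a)
    cb <- cumsum(tabulate(findInterval(b, br, all.inside = TRUE), bins)) / length(b)
    max(abs(ca - cb))
  }
  set.seed(2)
  worst <- 0
  for (rep_ in 1:5) {
    arr <- array(runif(63 * 63 * 4), dim = c(63, 63, 4))
    e <- enhance_sequence(morphodyn:::new_roi_sequence(arr, "windowed", 1L, 1:4))
    for (t in 2:4) {
      worst <- max(worst, binned_ks(as.vector(unclass(e)[, , t]),
                                    as.vector(unclass(e)[, , 1])))
    }
  }
  expect_lte(worst, 2 / 256)
})

test_that("every stage keeps values in [0, 1] and advances the stage tag", {
  roi <- random_roi(seed = 9)
  cfg <- preprocess_config()
  s1 <- invert_roi(roi)
  s2 <- suppress_background(s1, cfg)
  s3 <- gaussian_window(s2, cfg)
  s4 <- enhance_sequence(s3, cfg)
  for (s in list(s1, s2, s3, s4)) {
    expect_gte(min(unclass(s)), 0)
    expect_lte(max(unclass(s)), 1)
  }
  expect_equal(c(attr(s1, "stage"), attr(s2, "stage"), attr(s3, "stage"),
                 attr(s4, "stage")),
               c("inverted", "suppressed", "windowed", "enhanced"))
  expect_equal(attr(preprocess(roi, cfg), "stage"), "enhanced")
  expect_equal(attr(preprocess(roi, cfg, "no_preprocessing"), "stage"),
               "inverted")
})

test_that("the suppression pipeline is exactly bias-invariant; inversion alone is not", {
  roi <- random_roi(frames = 6, seed = 1, max_level = 0.5)  # headroom for +0.5
  cfg <- preprocess_config()
  p0 <- preprocess(roi, cfg)
  for (b in c(0.3, 0.5)) {
    pb <- preprocess(inject_bias(roi, b), cfg)
    expect_identical(as.vector(unclass(p0)), as.vector(unclass(pb)))
  }
  n0 <- preprocess(roi, cfg, "no_preprocessing")
  nb <- preprocess(inject_bias(roi, 0.3), cfg, "no_preprocessing")
  expect_equal(max(abs((unclass(nb) - unclass(n0)) + 0.3)), 0, tolerance = 1e-12)
})

test_that("enhancing an already-enhanced sequence barely changes it", {
  set.seed(13)
  raw <- array(runif(63 * 63 * 4, 0.2, 0.8), dim = c(63, 63, 4))
  e1 <- preprocess(morphodyn:::new_roi_sequence(raw, "raw", 1L, 1:4),
                   preprocess_config())
  e2 <- enhance_sequence(morphodyn:::advance_stage(e1, unclass(e1), "windowed"))
  expect_lt(max(abs(unclass(e2) - unclass(e1))), 1 / 256 + 1e-9)
})
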