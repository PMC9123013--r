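test_that("named backbones have the published feature dimensionalities", {
  expect_identical(backbone_dim("alexnet"), 9216L)
  expect_identical(backbone_dim("googlenet"), 1024L)
  expect_identical(backbone_dim("resnet101"), 2048L)
  expect_identical(backbone_dim("nasnetlarge"), 4032L)
  expect_error(backbone_dim("vgg16"), "unknown")
  # input sizes are part of the contract
  expect_equal(backbone_spec("alexnet")$input_size, 227L)
  expect_equal(backbone_spec("googlenet")$input_size, 224L)
  expect_equal(backbone_spec("resnet101")$input_size, 224L)
  expect_equal(backbone_spec("nasnetlarge")$input_size, 331L)
})

test_that("a named backbone without weights fails with remediation advice", {
  roi <- preprocess(random_roi(frames = 3), preprocess_config())
  expect_error(backbone_features(roi, backbone_spec("resnet101")),
               "fallback")
  # and allow_fallback substitutes the filter bank
  out <- backbone_features(roi, backbone_spec("resnet101",
                                              allow_fallback = TRUE))
  expect_equal(out$backbone, "fallback")
})

test_that("the fallback backbone is deterministic and NaN-free", {
  roi <- preprocess(random_roi(frames = 4, seed = 31), preprocess_config())
  a <- backbone_features(roi, backbone_spec("fallback", seed = 7))
  b <- backbone_features(roi, backbone_spec("fallback", seed = 7))
  expect_identical(a$signals, b$signals)
  expect_equal(nrow(a$signals), fallback_dim())
  expect_equal(ncol(a$signals), 4L)
  z <- backbone_features(
    morphodyn:::new_roi_sequence(array(0, c(63, 63, 3)), "inverted", 2L, 1:3),
    backbone_spec())
  expect_true(all(is.finite(z$signals)))
  # projected variant: same contract at a configured dimension
  p1 <- backbone_features(roi, backbone_spec("fallback", dim = 64L, seed = 7))
  p2 <- backbone_features(roi, backbone_spec("fallback", dim = 64L, seed = 7))
  expect_identical(p1$signals, p2$signals)
  expect_equal(nrow(p1$signals), 64L)
})

test_that("raw ROI sequences are rejected by the backbone", {
  expect_error(backbone_features(random_roi(), backbone_spec()), "preprocess")
})

test_that("the dynamics descriptor is the sample standard deviation", {
  s <- structure(list(
    signals = matrix(c(0, 1, 0, 1,
                       5, 5, 5, 5,
                       0, 0, 0, 0), 3, 4, byrow = TRUE),
    feature_ids = c("a", "b", "c"), track_id = 1L, frames = 1:4,
    backbone = "fallback"), class = "feature_signals")
  d <- dynamics_descriptor(s)
  expect_equal(unname(d["a"]), sd(c(0, 1, 0, 1)))
  expect_equal(round(unname(d["a"]), 4), 0.5774)
  expect_equal(unname(d["b"]), 0)
  expect_false("c" %in% names(d))            # all-zero feature dropped
  expect_equal(attr(d, "zero_mask"), c(FALSE, FALSE, TRUE))
  # coefficient-of-variation option
  dcv <- dynamics_descriptor(s, type = "cv")
  expect_equal(unname(dcv["a"]), sd(c(0, 1, 0, 1)) / 0.5)
  # single-frame track: dynamics undefined
  s1 <- s; s1$signals <- s$signals[, 1, drop = FALSE]
  expect_error(dynamics_descriptor(s1), "single-frame")
})
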