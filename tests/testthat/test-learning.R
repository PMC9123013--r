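test_that("feature_auc equals exhaustive pair counting, ties included", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    v <- sample(round(rnorm(n), 1))   # rounding forces ties
    y <- factor(c(rep("A", ceiling(n / 2)), rep("B", floor(n / 2))))
    expect_equal(feature_auc(v, y), brute_auc(v, y), tolerance = 1e-12)
  }
})

test_that("feature_auc matches the worked examples and symmetry", {
  y <- factor(c("A", "A", "B", "B"))
  expect_equal(feature_auc(c(1, 2, 1.5, 3), y), 0.75)
  expect_equal(feature_auc(c(1, 2, 5, 6), y), 1)
  expect_equal(feature_auc(-c(1, 2, 1.5, 3), y), 1 - 0.75)
  expect_error(feature_auc(1:4, factor(rep("A", 4))), "two classes")
})

test_that("selection applies the documented quantile thresholds", {
  aucs <- seq(0.30, 0.49, by = 0.01)
  s <- select_features(aucs, selection_config())
  th <- quantile(aucs, c(0.1, 0.9), type = 7)
  expect_equal(sort(s$selected), sort(which(aucs < th[1] | aucs > th[2])))
  expect_equal(s$th_min, unname(th[1]))
  expect_equal(s$th_max, unname(th[2]))
  expect_false(s$fallback)
})

test_that("a strongly discriminative feature always survives selection", {
  set.seed(3)
  hits <- 0
  for (r in 1:100) {
    aucs <- c(0.95, runif(99, 0.45, 0.55))
    if (1L %in% select_features(aucs)$selected) hits <- hits + 1
  }
  expect_equal(hits, 100)
})

test_that("identical AUCs fall back to top-k and are flagged", {
  s <- select_features(rep(0.5, 20), selection_config())
  expect_true(s$fallback)
  expect_gte(length(s$selected), 1L)
})

test_that("multi-class selection scores use the largest one-vs-rest deviation", {
  set.seed(9)
  y <- factor(rep(c("A", "B", "C"), each = 10))
  x <- cbind(sep = c(rnorm(10, 0), rnorm(10, 5), rnorm(10, 0)),
             noise = rnorm(30))
  sc <- selection_scores(x, y)
  expect_gt(sc["sep"], 0.9)
  expect_lt(abs(sc["noise"] - 0.5), 0.35)
})

test_that("linearly separable descriptors give perfect training accuracy", {
  d <- toy_descriptors()
  fp <- fit_predict(d, d, classifier_spec("svm"), selection_config())
  expect_equal(as.character(fp$labels), as.character(d$meta$label))
})

test_that("all four classifier kinds are deterministic given the seed", {
  d <- toy_descriptors(n_per_class = 12L, p = 20L)
  tr <- morphodyn:::subset_descriptors(d, c(1:8, 13:20))
  te <- morphodyn:::subset_descriptors(d, c(9:12, 21:24))
  for (kind in c("svm", "rf", "lda", "knn")) {
    spec <- classifier_spec(kind, seed = 5L,
                            rf_variant = "classical")
    a <- fit_predict(tr, te, spec, selection_config())
    b <- fit_predict(tr, te, spec, selection_config())
    expect_identical(a$labels, b$labels)
    expect_identical(a$scores, b$scores)
  }
  # boosted variant too
  spec <- classifier_spec("rf", seed = 5L, rf_variant = "boosted")
  a <- fit_predict(tr, te, spec, selection_config())
  b <- fit_predict(tr, te, spec, selection_config())
  expect_identical(a$labels, b$labels)
})

test_that("KNN is restricted to its top |AUC - 0.5| feature fraction", {
  d <- toy_descriptors(n_per_class = 12L, p = 40L)
  spec <- classifier_spec("knn", knn_fraction = 0.05)
  fp <- fit_predict(d, d, spec, selection_config())
  expect_s3_class(fp$labels, "factor")
  expect_equal(length(fp$labels), nrow(d$x))
})

test_that("training folds with a single class are rejected", {
  d <- toy_descriptors()
  bad <- morphodyn:::subset_descriptors(d, 1:16)   # class A only
  expect_error(fit_predict(bad, d, classifier_spec("lda")), "two classes")
})
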