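test_that("unbalanced accuracy is trace over total", {
  expect_equal(unbalanced_accuracy(matrix(c(28, 12, 7, 51), 2, 2)), 79 / 98)
  expect_equal(unbalanced_accuracy(diag(c(5, 9))), 1)
  expect_equal(unbalanced_accuracy(matrix(c(0, 3, 4, 0), 2, 2)), 0)
  expect_error(unbalanced_accuracy(matrix(0, 2, 2)), "empty")
})

test_that("cluster voting takes the modal label and breaks ties by score", {
  pred <- factor(c("A", "A", "B"), levels = c("A", "B"))
  sc <- matrix(0, 3, 2, dimnames = list(NULL, c("A", "B")))
  v <- cluster_vote(pred, sc, rep("c1", 3))
  expect_equal(as.character(v$label), "A")
  expect_false(v$tie)
  # tie: summed scores decide
  pred2 <- factor(c("A", "B"), levels = c("A", "B"))
  sc2 <- rbind(c(A = 0.2, B = 0), c(A = 0, B = 0.9))
  v2 <- cluster_vote(pred2, sc2, rep("c1", 2))
  expect_true(v2$tie)
  expect_equal(as.character(v2$label), "B")
  # tie with equal scores: lexicographic
  sc3 <- matrix(0.5, 2, 2, dimnames = list(NULL, c("A", "B")))
  v3 <- cluster_vote(pred2, sc3, rep("c1", 2))
  expect_equal(as.character(v3$label), "A")
})

test_that("Monte-Carlo cluster voting approaches the binomial closed form", {
  p <- 0.7
  exact <- sum(vapply(3:5, function(k) choose(5, k) * p^k * (1 - p)^(5 - k),
                      numeric(1)))
  expect_equal(exact, 0.83692)
  set.seed(123)
  correct <- colSums(matrix(runif(5 * 1e5) < p, nrow = 5)) >= 3
  expect_lt(abs(mean(correct) - exact), 0.005)
})

test_that("half-experiment-out folds never leak clusters and number two", {
  d <- toy_descriptors()
  rep_ <- half_experiment_out_cv(d, classifier_spec("lda"), selection_config())
  expect_equal(length(rep_$folds), 2L)
  for (f in rep_$folds) {
    test_keys <- unique(paste(f$predictions$video, f$predictions$cluster_id))
    train_keys <- setdiff(unique(paste(d$meta$video, d$meta$cluster_id)),
                          test_keys)
    expect_equal(length(intersect(test_keys, train_keys)), 0L)
    expect_equal(sum(f$confusion), nrow(f$predictions))
  }
  # separable toy data classifies perfectly across sides
  expect_gte(rep_$track$accuracy_mean, 0.95)
  expect_gte(rep_$cluster$accuracy_mean, rep_$track$accuracy_mean - 1e-9)
})

test_that("a video with all clusters on one side is rejected", {
  d <- toy_descriptors()
  d$meta$centroid_x[d$meta$video == "v1"] <- 100   # all left
  expect_error(half_experiment_out_cv(d, classifier_spec("lda")), "one side")
})

test_that("single-time-point analysis counts every frame once, no leakage", {
  d <- toy_descriptors(n_per_class = 8L, p = 12L)
  set.seed(31)
  signals <- lapply(seq_len(nrow(d$x)), function(i) {
    structure(list(signals = matrix(rnorm(12 * 6,
                                          mean = as.integer(d$meta$label[i])),
                                    12, 6),
                   feature_ids = paste0("f", 1:12), track_id = i, frames = 1:6,
                   backbone = "fallback"), class = "feature_signals")
  })
  rep_ <- single_timepoint_baseline(signals, d$meta, classifier_spec("lda"),
                                    selection_config())
  expect_equal(rep_$level, "single-time-point")
  expect_equal(rep_$n_instances, 16L * 6L)
  expect_equal(sum(rep_$track$confusion), 16L * 6L)
})

test_that("PCA scores are orthogonal with non-increasing explained variance", {
  d <- toy_descriptors()
  sc <- pca_scores(d, n_components = 3L)
  expect_lt(abs(sum(sc$PC1 * sc$PC2)), 1e-8)
  expect_lt(abs(sum(sc$PC1 * sc$PC3)), 1e-8)
  ev <- attr(sc, "explained")
  expect_true(all(diff(ev) <= 1e-12))
  # well-separated classes: silhouette of the 2-D scores above 0.3
  x2 <- cbind(sc$PC1, sc$PC2)
  sil <- vapply(seq_len(nrow(x2)), function(i) {
    own <- sc$label == sc$label[i]
    a <- mean(sqrt(rowSums((x2[own & seq_len(nrow(x2)) != i, , drop = FALSE] -
                              matrix(x2[i, ], sum(own) - 1, 2, byrow = TRUE))^2)))
    b <- mean(sqrt(rowSums((x2[!own, , drop = FALSE] -
                              matrix(x2[i, ], sum(!own), 2, byrow = TRUE))^2)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.3)
  meta5 <- toy_descriptors(8L, 5L)$meta[1:5, ]
  expect_error(pca_scores(track_descriptors(matrix(1, 5, 3), meta5)),
               "constant")
})

test_that("voting lifts accuracy when tracks err independently above chance", {
  set.seed(77)
  lv <- c("A", "B")
  n_clusters <- 200L
  size <- 5L
  p <- 0.75
  truth <- factor(rep(lv, each = n_clusters / 2 * size), levels = lv)
  flip <- runif(n_clusters * size) > p
  pred <- factor(ifelse(flip, ifelse(truth == "A", "B", "A"),
                        as.character(truth)), levels = lv)
  cl <- rep(seq_len(n_clusters), each = size)
  v <- cluster_vote(pred, matrix(0, length(pred), 2,
                                 dimnames = list(NULL, lv)), cl, truth)
  track_acc <- mean(pred == truth)
  cluster_acc <- mean(v$label == v$truth)
  expect_gt(cluster_acc, track_acc)
})

test_that("only temporal structure separates rate-contrast classes: dynamics succeed, single frames fail", {
  # two classes with the SAME stationary boundary-perturbation amplitude but
  # different fluctuation rates: per-frame shape distributions coincide, so
  # a single-time-point classifier has nothing to use, while the temporal
  # standard deviation of the feature signals still separates the classes
  exp_ <- run_synthetic_experiment(
    class_params = list(list(fluctuation_amplitude = 0.25, fluctuation_rate = 0.02),
                        list(fluctuation_amplitude = 0.25, fluctuation_rate = 0.6)),
    n_videos_per_class = 1L, n_clusters = 4L, cells_per_cluster = 5L,
    n_frames = 40L, seed = 21L, use_truth_tracks = TRUE)
  sigs <- experiment_signals(exp_)
  desc <- do.call(rbind, lapply(sigs, function(s) {
    d <- dynamics_descriptor(s)
    full <- stats::setNames(numeric(length(s$feature_ids)), s$feature_ids)
    full[names(d)] <- d
    full
  }))
  rownames(desc) <- NULL
  d <- track_descriptors(desc, exp_$meta)
  r <- half_experiment_out_cv(d, classifier_spec("svm"), selection_config())
  stp <- single_timepoint_baseline(sigs, exp_$meta, classifier_spec("svm"),
                                   selection_config())
  expect_gte(r$track$accuracy_mean, 0.9)
  expect_lt(abs(stp$track$accuracy_mean - 0.5),
            3 * sqrt(0.25 / nrow(exp_$meta)))

  # feature-level view of the same premise: the best sd-descriptor feature
  # separates the classes (AUC far from 0.5) while time-averaged feature
  # means hover near chance
  sd_auc <- selection_scores(desc[, apply(desc != 0, 2, any)], d$meta$label)
  mean_desc <- do.call(rbind, lapply(sigs, function(s) rowMeans(s$signals)))
  mean_auc <- selection_scores(mean_desc[, apply(mean_desc != 0, 2, any)],
                               d$meta$label)
  expect_gt(max(abs(sd_auc - 0.5)), 0.3)        # AUC > 0.8 or < 0.2
  expect_lt(median(abs(mean_auc - 0.5)), 0.15)
})
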