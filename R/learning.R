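#' AUC-quantile feature-selection configuration
#'
#' Features whose class-separation AUC lies below the `q_low` empirical
#' quantile or above the `q_high` quantile of all feature AUCs are selected:
#' the extremes on both sides are the discriminative ones (an AUC well below
#' 0.5 separates classes just as well as one above, with the sign flipped).
#'
#' @param q_low,q_high quantile levels for the thresholds
#'   `th_min = quantile(AUC, q_low)` and `th_max = quantile(AUC, q_high)`.
#' @param fallback_k when every AUC is identical (degenerate), fall back to
#'   the top-`fallback_k` features by `|AUC - 0.5|`.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(q_low = 0.1, q_high = 0.9, fallback_k = 10L) {
  stopifnot(q_low >= 0, q_low < q_high, q_high <= 1, fallback_k >= 1L)
  structure(list(q_low = q_low, q_high = q_high,
                 fallback_k = as.integer(fallback_k)),
            class = "selection_config")
}

#' Classifier specification
#'
#' @param kind one of `"svm"` (linear kernel), `"rf"` (tree ensemble),
#'   `"lda"` (diagonal-covariance linear discriminant), `"knn"`.
#' @param cost SVM regularisation constant C.
#' @param rf_variant `"boosted"` (gradient-boosted trees, tuned over
#'   ensemble cycles, tree depth and shrinkage learning rate by inner 5-fold
#'   cross-validation) or `"classical"` (random forest).
#' @param knn_k number of neighbours (odd).
#' @param knn_fraction fraction of features (ranked by `|AUC - 0.5|` on the
#'   training fold) the KNN model is restricted to.
#' @param seed integer seed for any stochastic fitting step.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "rf", "lda", "knn"), cost = 1,
                            rf_variant = c("boosted", "classical"),
                            knn_k = 9L, knn_fraction = 0.025, seed = 1L) {
  kind <- match.arg(kind)
  rf_variant <- match.arg(rf_variant)
  stopifnot(cost > 0, knn_k %% 2L == 1L, knn_fraction > 0, knn_fraction <= 1)
  structure(list(kind = kind, cost = cost, rf_variant = rf_variant,
                 knn_k = as.integer(knn_k), knn_fraction = knn_fraction,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Area under the ROC curve of one feature
#'
#' Computed as the normalised Mann-Whitney pair statistic
#' `P(value_pos > value_neg) + 0.5 P(tie)`, with the second factor level of
#' `labels` taken as the positive class.
#'
#' @param values numeric feature values.
#' @param labels two-level factor (or coercible) of the same length.
#' @return AUC in `[0, 1]`.
#' @export
feature_auc <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) {
    stop("feature_auc requires exactly two classes with members; got ",
         nlevels(droplevels(labels)))
  }
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) stop("feature_auc requires both classes present")
  pos <- values[labels == levels(labels)[2L]]
  neg <- values[labels == levels(labels)[1L]]
  r <- rank(c(pos, neg))   # midranks handle ties as half-concordant pairs
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Per-feature selection score
#'
#' Binary problems use the raw AUC. With more than two classes, one-vs-rest
#' AUCs are computed per feature and the largest deviation `|AUC - 0.5|` is
#' used as the score (mapped back to the `0.5 + |dev|` scale so that the
#' quantile-threshold rule still reads "keep the extremes").
#'
#' @param x feature matrix (rows = instances).
#' @param y class labels.
#' @return numeric vector of per-feature scores on the AUC scale.
#' @export
selection_scores <- function(x, y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) == 2L) {
    apply(x, 2, feature_auc, labels = y)
  } else {
    apply(x, 2, function(col) {
      devs <- vapply(levels(y), function(lv) {
        abs(feature_auc(col, factor(y == lv, levels = c(FALSE, TRUE))) - 0.5)
      }, numeric(1))
      0.5 + max(devs)
    })
  }
}

#' Select features by AUC quantile thresholds
#'
#' @param aucs per-feature AUC values (or selection scores).
#' @param config a [selection_config()].
#' @return list with `selected` (integer indices), `th_min`, `th_max` and
#'   `fallback` (TRUE when the degenerate top-k path was taken).
#' @export
select_features <- function(aucs, config = selection_config()) {
  stopifnot(length(aucs) >= 2L)
  th <- stats::quantile(aucs, c(config$q_low, config$q_high), names = FALSE,
                        type = 7)
  sel <- which(aucs < th[1] | aucs > th[2])
  if (length(sel) == 0L) {
    k <- min(config$fallback_k, length(aucs))
    sel <- order(abs(aucs - 0.5), decreasing = TRUE)[seq_len(k)]
    return(list(selected = sort(sel), th_min = th[1], th_max = th[2],
                fallback = TRUE))
  }
  list(selected = sel, th_min = th[1], th_max = th[2], fallback = FALSE)
}

#' Assemble a track-descriptor set
#'
#' @param x numeric matrix, one row per track.
#' @param meta data.frame with one row per track: `track_id`, `video`,
#'   `cluster_id`, `label`, `centroid_x`, `midline` (the frame's vertical
#'   midline, px).
#' @return object of class `track_descriptors`.
#' @export
track_descriptors <- function(x, meta) {
  stopifnot(is.matrix(x), nrow(x) == nrow(meta),
            all(c("track_id", "video", "cluster_id", "label", "centroid_x",
                  "midline") %in% names(meta)))
  meta$label <- as.factor(meta$label)
  structure(list(x = x, meta = meta), class = "track_descriptors")
}

#' @export
print.track_descriptors <- function(x, ...) {
  cat(sprintf("track_descriptors: %d tracks x %d features, %d video(s), %d cluster(s)\n",
              nrow(x$x), ncol(x$x), length(unique(x$meta$video)),
              length(unique(paste(x$meta$video, x$meta$cluster_id)))))
  print(table(x$meta$label))
  invisible(x)
}

subset_descriptors <- function(d, idx) {
  track_descriptors(d$x[idx, , drop = FALSE], d$meta[idx, , drop = FALSE])
}

zscore_fit <- function(x) {
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  list(mu = mu, sd = sd_)
}
zscore_apply <- function(x, z) sweep(sweep(x, 2, z$mu), 2, z$sd, "/")

# diagonal-covariance linear discriminant analysis: pooled per-feature
# variances, Gaussian class-conditional densities with diagonal covariance
diag_lda_fit <- function(x, y) {
  lv <- levels(y)
  mu <- t(vapply(lv, function(l) colMeans(x[y == l, , drop = FALSE]),
                 numeric(ncol(x))))
  pooled <- Reduce(`+`, lapply(lv, function(l) {
    xs <- x[y == l, , drop = FALSE]
    sweep(xs, 2, colMeans(xs))^2
  }))
  v <- colSums(pooled) / (nrow(x) - length(lv))
  v[v <= 0 | !is.finite(v)] <- 1e-12
  prior <- as.numeric(table(y)[lv]) / nrow(x)
  list(levels = lv, mu = mu, var = v, prior = prior)
}
diag_lda_scores <- function(fit, x) {
  sc <- vapply(seq_along(fit$levels), function(k) {
    -0.5 * colSums((t(x) - fit$mu[k, ])^2 / fit$var) + log(fit$prior[k])
  }, numeric(nrow(x)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = nrow(x))
  colnames(sc) <- fit$levels
  sc
}

tune_boosted <- function(x, y, seed) {
  ylab <- as.integer(y) - 1L
  nclass <- nlevels(y)
  params_common <- if (nclass == 2L) {
    list(objective = "binary:logistic", eval_metric = "error")
  } else {
    list(objective = "multi:softprob", num_class = nclass,
         eval_metric = "merror")
  }
  grid <- expand.grid(max_depth = c(2L, 4L), eta = c(0.1, 0.3),
                      nrounds = c(50L, 150L))
  dtrain <- xgboost::xgb.DMatrix(x, label = ylab, nthread = 1L)
  best <- NULL; best_err <- Inf
  for (i in seq_len(nrow(grid))) {
    set.seed(seed)
    cv <- xgboost::xgb.cv(params = c(params_common,
                                     list(max_depth = grid$max_depth[i],
                                          eta = grid$eta[i], nthread = 1L)),
                          data = dtrain, nrounds = grid$nrounds[i],
                          nfold = 5L, verbose = 0L, stratified = TRUE)
    log <- cv$evaluation_log
    err <- min(log[[grep("^test_.*_mean$", names(log), value = TRUE)[1]]])
    if (err < best_err) { best_err <- err; best <- grid[i, ] }
  }
  best
}

#' Train a classifier on a training fold and predict a test fold
#'
#' Feature selection (AUC quantile thresholds) and standardisation are fitted
#' on the training descriptors only and applied to the test descriptors, so
#' leakage is impossible through this interface. KNN is additionally
#' restricted to its top `knn_fraction` features ranked by `|AUC - 0.5|` on
#' the training fold.
#'
#' @param train,test `track_descriptors` objects.
#' @param spec a [classifier_spec()].
#' @param selection a [selection_config()].
#' @return list with `labels` (factor of test predictions), `scores` (matrix
#'   test tracks x classes; larger = more support), `selection` (the
#'   [select_features()] result), `selected_names` and `spec`.
#' @export
fit_predict <- function(train, test, spec = classifier_spec(),
                        selection = selection_config()) {
  stopifnot(inherits(train, "track_descriptors"),
            inherits(test, "track_descriptors"))
  y <- droplevels(train$meta$label)
  if (nlevels(y) < 2L) stop("training fold has fewer than two classes")
  nonzero <- which(apply(train$x != 0, 2, any))
  if (length(nonzero) < 2L) stop("training descriptors are all zero")
  xtr_all <- train$x[, nonzero, drop = FALSE]
  xte_all <- test$x[, nonzero, drop = FALSE]

  aucs <- selection_scores(xtr_all, y)
  sel <- select_features(aucs, selection)
  if (length(sel$selected) == 0L) {
    stop("AUC-quantile selection returned no features and the top-k ",
         "fallback is exhausted")
  }
  xtr <- xtr_all[, sel$selected, drop = FALSE]
  xte <- xte_all[, sel$selected, drop = FALSE]
  z <- zscore_fit(xtr)
  xtr <- zscore_apply(xtr, z)
  xte <- zscore_apply(xte, z)
  lv <- levels(y)

  scores <- switch(spec$kind,
    svm = {
      set.seed(spec$seed)
      fit <- e1071::svm(xtr, y, kernel = "linear", cost = spec$cost,
                        scale = FALSE)
      pr <- stats::predict(fit, xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      sc <- matrix(0, nrow(xte), length(lv), dimnames = list(NULL, lv))
      for (cn in colnames(dv)) {
        pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
        sc[, pair[1]] <- sc[, pair[1]] + dv[, cn]
        sc[, pair[2]] <- sc[, pair[2]] - dv[, cn]
      }
      sc
    },
    rf = {
      if (spec$rf_variant == "classical") {
        set.seed(spec$seed)
        fit <- randomForest::randomForest(xtr, y, ntree = 500L)
        stats::predict(fit, xte, type = "prob")[, lv, drop = FALSE]
      } else {
        best <- tune_boosted(xtr, y, spec$seed)
        set.seed(spec$seed)
        nclass <- length(lv)
        params <- if (nclass == 2L) {
          list(objective = "binary:logistic")
        } else {
          list(objective = "multi:softprob", num_class = nclass)
        }
        dtr <- xgboost::xgb.DMatrix(xtr, label = as.integer(y) - 1L,
                                    nthread = 1L)
        fit <- xgboost::xgb.train(params = c(params,
                                             list(max_depth = best$max_depth,
                                                  eta = best$eta,
                                                  nthread = 1L)),
                                  data = dtr, nrounds = best$nrounds,
                                  verbose = 0L)
        pr <- stats::predict(fit, xgboost::xgb.DMatrix(xte, nthread = 1L))
        if (nclass == 2L) {
          cbind(`1` = 1 - pr, `2` = pr) -> sc
          colnames(sc) <- lv
          sc
        } else {
          matrix(pr, ncol = nclass, byrow = TRUE, dimnames = list(NULL, lv))
        }
      }
    },
    lda = {
      fit <- diag_lda_fit(xtr, y)
      diag_lda_scores(fit, xte)
    },
    knn = {
      k_feat <- max(1L, round(spec$knn_fraction * ncol(xtr_all)))
      ranked <- order(abs(aucs - 0.5), decreasing = TRUE)[seq_len(k_feat)]
      xs <- zscore_fit(xtr_all[, ranked, drop = FALSE])
      a <- zscore_apply(xtr_all[, ranked, drop = FALSE], xs)
      b <- zscore_apply(xte_all[, ranked, drop = FALSE], xs)
      set.seed(spec$seed)
      pr <- class::knn(a, b, y, k = spec$knn_k, prob = TRUE)
      sc <- matrix(0, nrow(b), length(lv), dimnames = list(NULL, lv))
      p <- attr(pr, "prob")
      for (i in seq_len(nrow(b))) sc[i, as.character(pr[i])] <- p[i]
      sc
    }
  )
  labels <- factor(lv[max.col(scores, ties.method = "first")], levels = lv)
  list(labels = labels, scores = scores, selection = sel,
       selected_names = colnames(xtr_all)[sel$selected], spec = spec)
}
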