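#' Unbalanced accuracy of a confusion matrix
#'
#' The ratio of the sum of correctly classified instances (the confusion
#' matrix trace) over the total number of instances — no per-class
#' reweighting.
#'
#' @param confusion square count matrix (rows = truth, columns = predicted).
#' @return fraction in `[0, 1]`.
#' @export
unbalanced_accuracy <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion),
            all(confusion >= 0))
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(confusion)) / total
}

confusion_matrix <- function(truth, pred, levels_) {
  table(factor(truth, levels = levels_), factor(pred, levels = levels_))
}

#' Majority voting over the tracks of each cluster
#'
#' Assigns one class to every spatial cluster: the modal label among its
#' tracks' predictions. Ties are resolved by the larger summed classifier
#' score, then lexicographically; tied clusters are flagged.
#'
#' @param pred factor of per-track predicted labels.
#' @param scores matrix tracks x classes of classifier support.
#' @param cluster per-track cluster key (same length as `pred`).
#' @param truth optional per-track true labels (tracks of a cluster share
#'   their class).
#' @return data.frame with one row per cluster: `cluster`, `label`, `tie`,
#'   and `truth` when provided.
#' @export
cluster_vote <- function(pred, scores, cluster, truth = NULL) {
  stopifnot(length(pred) == length(cluster))
  lv <- levels(pred)
  keys <- unique(cluster)
  rows <- lapply(keys, function(k) {
    idx <- which(cluster == k)
    votes <- table(factor(pred[idx], levels = lv))
    top <- which(votes == max(votes))
    tie <- length(top) > 1L
    if (tie) {
      ssum <- colSums(scores[idx, , drop = FALSE])[names(votes)[top]]
      top <- top[order(-ssum, names(votes)[top])][1L]
    }
    data.frame(cluster = k, label = names(votes)[top[1L]], tie = tie,
               truth = if (is.null(truth)) NA_character_ else
                 as.character(truth[idx][1L]))
  })
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = lv)
  if (!is.null(truth)) out$truth <- factor(out$truth, levels = lv)
  out
}

cluster_side <- function(meta) {
  # a cluster's side of the frame: mean track centroid x vs the midline
  key <- paste(meta$video, meta$cluster_id, sep = "/")
  mean_x <- tapply(meta$centroid_x, key, mean)
  mid <- tapply(meta$midline, key, mean)
  side <- ifelse(mean_x < mid, "left", "right")
  for (v in unique(meta$video)) {
    ks <- unique(key[meta$video == v])
    if (length(unique(side[ks])) < 2L) {
      stop("video '", v, "' has all clusters on one side of the midline; ",
           "half-experiment-out folds are undefined")
    }
  }
  side[key]
}

#' Half-experiment-out cross-validation at the single-track level
#'
#' Every video is split at its vertical midline; each of the two folds uses
#' the clusters of one side (across all videos) as the test set and the
#' complementary clusters as training. Whole clusters move together, so no
#' cluster — and no spatial neighbourhood — is ever split between training
#' and test.
#'
#' @param descriptors a [track_descriptors()] set covering all videos.
#' @param spec a [classifier_spec()].
#' @param selection a [selection_config()].
#' @return object of class `evaluation_report`: list with `level`,
#'   `folds` (per-fold details incl. track- and cluster-level confusions),
#'   `track` and `cluster` summaries (`accuracy_mean`, `accuracy_sd`,
#'   pooled `confusion`), `classifier`.
#' @export
half_experiment_out_cv <- function(descriptors, spec = classifier_spec(),
                                   selection = selection_config()) {
  stopifnot(inherits(descriptors, "track_descriptors"))
  meta <- descriptors$meta
  side <- cluster_side(meta)
  lv <- levels(droplevels(meta$label))
  folds <- lapply(c("left", "right"), function(test_side) {
    te <- which(side == test_side)
    tr <- which(side != test_side)
    stopifnot(length(intersect(
      unique(paste(meta$video, meta$cluster_id)[te]),
      unique(paste(meta$video, meta$cluster_id)[tr]))) == 0L)
    fp <- fit_predict(subset_descriptors(descriptors, tr),
                      subset_descriptors(descriptors, te), spec, selection)
    truth <- factor(meta$label[te], levels = lv)
    conf <- confusion_matrix(truth, fp$labels, lv)
    ckey <- paste(meta$video, meta$cluster_id, sep = "/")[te]
    cv_ <- cluster_vote(fp$labels, fp$scores, ckey, truth)
    cconf <- confusion_matrix(cv_$truth, cv_$label, lv)
    list(test_side = test_side, confusion = conf,
         accuracy = unbalanced_accuracy(conf),
         cluster_confusion = cconf,
         cluster_accuracy = unbalanced_accuracy(cconf),
         predictions = data.frame(track_id = meta$track_id[te],
                                  video = meta$video[te],
                                  cluster_id = meta$cluster_id[te],
                                  truth = truth, pred = fp$labels),
         selection = fp$selection)
  })
  acc <- vapply(folds, `[[`, numeric(1), "accuracy")
  cacc <- vapply(folds, `[[`, numeric(1), "cluster_accuracy")
  structure(list(
    level = "single-track",
    folds = folds,
    track = list(accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
                 confusion = folds[[1]]$confusion + folds[[2]]$confusion),
    cluster = list(accuracy_mean = mean(cacc), accuracy_sd = stats::sd(cacc),
                   confusion = folds[[1]]$cluster_confusion +
                     folds[[2]]$cluster_confusion),
    classifier = spec$kind
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (%s, %s)\n", x$level, x$classifier))
  cat(sprintf("  single-track unbalanced accuracy: %.2f%% +/- %.2f%%\n",
              100 * x$track$accuracy_mean, 100 * x$track$accuracy_sd))
  if (!is.null(x$cluster)) {
    cat(sprintf("  cluster-level unbalanced accuracy: %.2f%% +/- %.2f%%\n",
                100 * x$cluster$accuracy_mean, 100 * x$cluster$accuracy_sd))
  }
  invisible(x)
}

#' Luminance-bias sensitivity protocol
#'
#' Trains on unbiased ROIs and evaluates on test ROIs with a fixed luminance
#' bias injected, for every combination of bias level and preprocessing mode.
#' With background suppression (and no pixel clipping) the descriptors of
#' biased and unbiased ROIs are identical, so the accuracy column is constant;
#' without preprocessing the bias shifts every feature and accuracy collapses
#' as the bias grows.
#'
#' @param rois list of raw `roi_sequence` objects, one per track.
#' @param meta per-track metadata (as for [track_descriptors()]).
#' @param biases graylevel offsets applied to test ROIs.
#' @param modes preprocessing arms to compare.
#' @param backbone a [backbone_spec()].
#' @param spec a [classifier_spec()].
#' @param selection a [selection_config()].
#' @param config a [preprocess_config()].
#' @param clip clamp biased pixels to `[0, 1]`; keep `FALSE` to study the
#'   pure additive offset without saturation effects.
#' @return data.frame with columns `mode`, `bias`, `accuracy_mean`,
#'   `accuracy_sd` (over the two folds).
#' @export
bias_sensitivity <- function(rois, meta, biases = c(0, 0.3, 0.5),
                             modes = c("background_suppression",
                                       "no_preprocessing"),
                             backbone = backbone_spec(),
                             spec = classifier_spec(),
                             selection = selection_config(),
                             config = preprocess_config(), clip = FALSE) {
  stopifnot(length(rois) == nrow(meta))
  side <- cluster_side(meta)
  lv <- levels(droplevels(as.factor(meta$label)))
  out <- list()
  for (mode in modes) {
    # training descriptors: unbiased, this mode
    base_desc <- descriptor_matrix(rois, backbone, config, mode)
    train_desc <- track_descriptors(base_desc, meta)
    # test descriptors per bias
    for (b in biases) {
      xb <- if (b == 0) base_desc else
        descriptor_matrix(lapply(rois, inject_bias, bias = b, clip = clip),
                          backbone, config, mode)
      test_desc <- track_descriptors(xb, meta)
      accs <- vapply(c("left", "right"), function(ts) {
        te <- which(side == ts); tr <- which(side != ts)
        fp <- fit_predict(subset_descriptors(train_desc, tr),
                          subset_descriptors(test_desc, te), spec, selection)
        unbalanced_accuracy(confusion_matrix(
          factor(meta$label[te], levels = lv), fp$labels, lv))
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        mode = mode, bias = b, accuracy_mean = mean(accs),
        accuracy_sd = stats::sd(accs))
    }
  }
  do.call(rbind, out)
}

#' Deep-branch descriptor matrix for a set of ROI sequences
#'
#' Preprocesses every raw ROI sequence in the given mode, extracts backbone
#' feature signals and reduces them to the temporal-dynamics descriptor.
#' Features that are all-zero for a track contribute 0 (no dynamics).
#'
#' @param rois list of raw `roi_sequence` objects.
#' @param backbone a [backbone_spec()].
#' @param config a [preprocess_config()].
#' @param mode preprocessing arm.
#' @return numeric matrix, tracks x backbone features.
#' @export
descriptor_matrix <- function(rois, backbone = backbone_spec(),
                              config = preprocess_config(),
                              mode = "background_suppression") {
  rows <- lapply(rois, function(r) {
    sig <- backbone_features(preprocess(r, config, mode), backbone)
    d <- dynamics_descriptor(sig)
    full <- numeric(length(sig$feature_ids))
    names(full) <- sig$feature_ids
    full[names(d)] <- d
    full
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-time-point baseline
#'
#' Treats every frame of every track as one instance, described by its raw
#' per-frame backbone feature vector (no temporal statistic), and runs the
#' same selection + classification machinery under the same cluster-based
#' folds. No frame of a test track ever appears in training.
#'
#' @param signals list of `feature_signals`, one per track.
#' @param meta per-track metadata (as for [track_descriptors()]).
#' @param spec a [classifier_spec()].
#' @param selection a [selection_config()].
#' @return `evaluation_report` with level `"single-time-point"`; `n_instances`
#'   equals the total number of frames.
#' @export
single_timepoint_baseline <- function(signals, meta,
                                      spec = classifier_spec(),
                                      selection = selection_config()) {
  stopifnot(length(signals) == nrow(meta))
  side <- cluster_side(meta)
  lv <- levels(droplevels(as.factor(meta$label)))
  inst_x <- do.call(rbind, lapply(signals, function(s) t(s$signals)))
  inst_track <- rep(seq_along(signals),
                    vapply(signals, function(s) ncol(s$signals), integer(1)))
  inst_meta <- meta[inst_track, ]
  inst_side <- side[inst_track]
  folds <- lapply(c("left", "right"), function(ts) {
    te <- which(inst_side == ts); tr <- which(inst_side != ts)
    stopifnot(length(intersect(inst_track[te], inst_track[tr])) == 0L)
    fp <- fit_predict(
      track_descriptors(inst_x[tr, , drop = FALSE], inst_meta[tr, ]),
      track_descriptors(inst_x[te, , drop = FALSE], inst_meta[te, ]),
      spec, selection)
    truth <- factor(inst_meta$label[te], levels = lv)
    conf <- confusion_matrix(truth, fp$labels, lv)
    list(test_side = ts, confusion = conf,
         accuracy = unbalanced_accuracy(conf))
  })
  acc <- vapply(folds, `[[`, numeric(1), "accuracy")
  structure(list(level = "single-time-point", folds = folds,
                 track = list(accuracy_mean = mean(acc),
                              accuracy_sd = stats::sd(acc),
                              confusion = folds[[1]]$confusion +
                                folds[[2]]$confusion),
                 cluster = NULL, classifier = spec$kind,
                 n_instances = nrow(inst_x)),
            class = "evaluation_report")
}

#' PCA score coordinates of track descriptors
#'
#' Principal component analysis of the standardised descriptors, for score
#' scatter plots of the class structure.
#'
#' @param descriptors a [track_descriptors()] set.
#' @param n_components number of components to return.
#' @return data.frame of scores (`PC1`, `PC2`, ...) with `label`; attributes
#'   `explained` (variance fractions) and `rotation`.
#' @export
pca_scores <- function(descriptors, n_components = 2L) {
  stopifnot(inherits(descriptors, "track_descriptors"),
            nrow(descriptors$x) >= 3L)
  keep <- apply(descriptors$x, 2, stats::sd) > 0
  if (!any(keep)) stop("constant feature matrix: PCA undefined")
  p <- stats::prcomp(descriptors$x[, keep, drop = FALSE], center = TRUE,
                     scale. = TRUE)
  k <- min(n_components, ncol(p$x))
  out <- as.data.frame(p$x[, seq_len(k), drop = FALSE])
  out$label <- descriptors$meta$label
  structure(out,
            explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)],
            rotation = p$rotation[, seq_len(k), drop = FALSE])
}
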