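#' Published benchmark accuracies of the original platform
#'
#' The accuracy tables reported for the original colorectal-adenocarcinoma
#' case studies (DLD-1 vs LOX-1-inhibited, and the three-dose Bevacizumab
#' comparison), shipped as plain CSV. The source videos are not publicly
#' deposited, so these numbers cannot be recomputed; they are kept as
#' reference inputs for the self-contained arithmetic consistency checks
#' below and for comparing qualitative patterns (network spread, deep vs
#' traditional margin, bias stability) against synthetic runs.
#'
#' @return data.frame with columns `case_study`, `table`, `level`,
#'   `network`, `classifier`, `features`, `bias`, `mode`, `mean`, `sd`
#'   (accuracies in percent).
#' @export
reported_accuracies <- function() {
  utils::read.csv(system.file("extdata", "published_accuracy.csv",
                              package = "morphodyn"),
                  stringsAsFactors = FALSE)
}

#' Spread of single-track accuracy across backbone networks
#'
#' The largest minus the smallest mean single-track accuracy over the four
#' CNN backbones, for one case study — the "network invariance" margin
#' quoted alongside the published tables.
#'
#' @param case_study 1 or 2.
#' @param acc accuracy table (defaults to [reported_accuracies()]).
#' @return spread in accuracy percentage points.
#' @export
accuracy_spread <- function(case_study = 1, acc = reported_accuracies()) {
  rows <- acc[acc$case_study == case_study & acc$table %in% c(1, 4) &
                acc$level == "single_track", ]
  max(rows$mean) - min(rows$mean)
}

#' Margin of the dynamics descriptors over the traditional benchmark
#'
#' Mean single-track accuracy of the deep-dynamics branch (ResNet101
#' descriptors) minus the shape + texture benchmark, for one case study and
#' classifier.
#'
#' @param case_study 1 or 2.
#' @param classifier `"svm"`, `"rf"`, `"lda"` or `"knn"`.
#' @param level `"single_track"` or `"cluster"`.
#' @param acc accuracy table.
#' @return improvement in accuracy percentage points.
#' @export
accuracy_improvement <- function(case_study = 1, classifier = "svm",
                                 level = "single_track",
                                 acc = reported_accuracies()) {
  tab <- if (case_study == 1) c(1, 2) else c(4, 5)
  deep <- acc[acc$case_study == case_study & acc$table %in% tab &
                acc$level == level & acc$classifier == classifier &
                acc$features == "deep" & acc$network == "resnet101" &
                is.na(acc$bias), ]
  trad <- acc[acc$case_study == case_study & acc$level == level &
                acc$classifier == classifier & acc$features == "shape_texture", ]
  deep$mean[1] - trad$mean[1]
}

#' Published cluster-level confusion counts (first case study)
#'
#' Out of 35 clusters of the control line, 28 were recognised correctly and
#' 7 misassigned; out of 63 clusters of the knockdown line, 51 were correct
#' and 12 misassigned.
#'
#' @return 2x2 count matrix (rows = truth, columns = predicted).
#' @export
reported_cluster_confusion <- function() {
  matrix(c(28, 12, 7, 51), 2, 2,
         dimnames = list(truth = c("control", "knockdown"),
                         predicted = c("control", "knockdown")))
}

#' Physical area of a square ROI
#'
#' @param roi_px side length in pixels (default 63).
#' @param resolution micrometres per pixel (default 0.33).
#' @return area in square millimetres.
#' @export
roi_physical_area_mm2 <- function(roi_px = 63, resolution = 0.33) {
  (roi_px * resolution / 1000)^2
}

#' Convert pixels to micrometres
#'
#' @param px length in pixels.
#' @param resolution micrometres per pixel.
#' @return length in micrometres (e.g. the 18 px Gaussian window sigma is
#'   about 5.9 um at 0.33 um/px).
#' @export
px_to_um <- function(px, resolution = 0.33) px * resolution
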