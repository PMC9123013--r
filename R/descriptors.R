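#' Segment the central cell of a preprocessed ROI frame
#'
#' The segmenter is pluggable: the built-in `"otsu"` fallback thresholds the
#' (bright-cell) frame at Otsu's level, fills holes and keeps the connected
#' component closest to the crop centre. Any external mask provider (e.g. a
#' trained semantic-segmentation network) can be substituted by passing its
#' masks directly to [shape_texture_descriptor()].
#'
#' @param frame numeric matrix, a single preprocessed ROI frame (bright cell
#'   on dark background).
#' @param segmenter identifier; only `"otsu"` is built in.
#' @return logical matrix of the same size with attribute `empty` (TRUE when
#'   no foreground was found) and `segmenter`.
#' @export
segment_cell <- function(frame, segmenter = "otsu") {
  stopifnot(is.matrix(frame))
  if (!identical(segmenter, "otsu")) {
    stop("unknown segmenter '", segmenter, "'; supply masks from an external ",
         "provider directly to shape_texture_descriptor()")
  }
  rng <- range(frame)
  if (rng[2] - rng[1] < 1e-8) {
    mask <- matrix(FALSE, nrow(frame), ncol(frame))
    return(structure(mask, empty = TRUE, segmenter = segmenter))
  }
  thr <- EBImage::otsu(EBImage::Image(frame), range = rng)
  bw <- frame > thr
  bw <- EBImage::fillHull(EBImage::bwlabel(bw)) > 0
  lab <- EBImage::bwlabel(bw)
  n <- max(lab)
  if (n == 0) {
    return(structure(matrix(FALSE, nrow(frame), ncol(frame)),
                     empty = TRUE, segmenter = segmenter))
  }
  # keep the component nearest the crop centre (the tracked cell)
  cy <- (nrow(frame) + 1) / 2; cx <- (ncol(frame) + 1) / 2
  d2 <- vapply(seq_len(n), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    min((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
  }, numeric(1))
  mask <- lab == which.min(d2)
  structure(mask, empty = FALSE, segmenter = segmenter)
}

#' Segment every frame of a ROI sequence
#'
#' @param roi a preprocessed `roi_sequence`.
#' @param segmenter identifier passed to [segment_cell()].
#' @return list of logical masks, one per frame.
#' @export
segment_sequence <- function(roi, segmenter = "otsu") {
  stopifnot(inherits(roi, "roi_sequence"))
  arr <- unclass(roi)
  lapply(seq_len(dim(arr)[3]), function(t) segment_cell(arr[, , t], segmenter))
}

solidity_of_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(1)
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  hx <- idx[hull, 2]; hy <- idx[hull, 1]
  # rasterised convex area: pixels whose centres fall inside (or on) the
  # hull polygon, the usual pixel-count convention for solidity
  xr <- min(idx[, 2]):max(idx[, 2])
  yr <- min(idx[, 1]):max(idx[, 1])
  px <- rep(xr, each = length(yr))
  py <- rep(yr, times = length(xr))
  inside <- in_convex_hull(px, py, hx, hy)
  min(sum(mask) / max(sum(inside), 1), 1)
}

# point-in-convex-polygon: all cross products have the same sign (or zero)
in_convex_hull <- function(px, py, hx, hy) {
  n <- length(hx)
  j <- c(2:n, 1L)
  sgn <- sign(sum(hx * hy[j] - hx[j] * hy))   # polygon winding
  if (sgn == 0) sgn <- 1
  ok <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    k <- j[i]
    cr <- (hx[k] - hx[i]) * (py - hy[i]) - (hy[k] - hy[i]) * (px - hx[i])
    ok <- ok & (sgn * cr >= -1e-9)
  }
  ok
}

frame_shape_features <- function(mask) {
  lab <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  sh <- EBImage::computeFeatures.shape(lab)
  mo <- EBImage::computeFeatures.moment(lab)
  c(area = unname(sh[1, "s.area"]),
    perimeter = unname(sh[1, "s.perimeter"]),
    eccentricity = unname(mo[1, "m.eccentricity"]),
    solidity = solidity_of_mask(mask))
}

frame_haralick_features <- function(mask, frame, nbins = 64L) {
  lab <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  h <- EBImage::computeFeatures.haralick(lab, EBImage::Image(frame),
                                         haralick.nbins = nbins,
                                         haralick.scales = 1L)
  v <- h[1, ]
  names(v) <- sub("\\.s1$", "", names(v))
  v
}

signal_entropy <- function(x, bins = 32L) {
  if (length(unique(x)) == 1L) return(0)
  p <- tabulate(cut(x, breaks = bins, labels = FALSE), bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

trajectory_statistics <- function(x) {
  s <- stats::sd(x)
  # degenerate-moment convention: constant or too-short signals have their
  # higher moments reported as 0 rather than NaN
  sk <- if (is.finite(s) && s > 0 && length(x) >= 3L)
    e1071::skewness(x, type = 2) else 0
  ku <- if (is.finite(s) && s > 0 && length(x) >= 4L)
    e1071::kurtosis(x, type = 2) else 0
  c(mean = mean(x), sd = if (is.finite(s)) s else 0,
    skewness = sk, kurtosis = ku, entropy = signal_entropy(x))
}

#' Traditional shape + texture track descriptor
#'
#' The benchmark branch: per frame, four morphological descriptors of the
#' segmented cell (area, perimeter, eccentricity, solidity) and the 13
#' classical Haralick GLCM texture statistics inside the cell region
#' (distance 1, 4 directions averaged, 64 graylevels); each of the resulting
#' 17 per-frame signals is summarised by five trajectory statistics (mean,
#' standard deviation, skewness, kurtosis, Shannon entropy of the signal's
#' 32-bin value histogram), giving an 85-dimensional track descriptor.
#'
#' @param roi a preprocessed `roi_sequence`.
#' @param masks list of logical masks aligned with the frames (from
#'   [segment_sequence()] or an external segmenter).
#' @return named numeric vector of length 85 with attribute `track_id`.
#' @export
shape_texture_descriptor <- function(roi, masks = NULL) {
  stopifnot(inherits(roi, "roi_sequence"))
  arr <- unclass(roi)
  Tn <- dim(arr)[3]
  if (is.null(masks)) masks <- segment_sequence(roi)
  stopifnot(length(masks) == Tn)
  ok <- !vapply(masks, function(m) isTRUE(attr(m, "empty")) || sum(m) < 5,
                logical(1))
  if (sum(ok) < 2L) stop("fewer than two frames with a usable cell mask")
  feats <- vapply(which(ok), function(t) {
    c(frame_shape_features(masks[[t]]),
      frame_haralick_features(masks[[t]], arr[, , t]))
  }, numeric(17))
  stats_ <- apply(feats, 1, trajectory_statistics)   # 5 x 17
  out <- as.vector(stats_)
  names(out) <- as.vector(outer(rownames(stats_), colnames(stats_),
                                function(s, f) paste(f, s, sep = ".")))
  structure(out, track_id = attr(roi, "track_id"))
}
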