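#' Detection configuration for the Circular Hough Transform
#'
#' @param radius_range_um search range of cell radii in micrometres; the
#'   default `[4.3, 7.6]` um corresponds to roughly 13-23 px at 0.33 um/px.
#' @param resolution micrometres per pixel.
#' @param sensitivity accumulator threshold as a fraction of a complete circle
#'   of edge votes: a candidate centre is kept when its (smoothed) vote count
#'   exceeds `sensitivity * 2 * pi * r`. Lower values find fainter cells.
#' @param grad_threshold minimum gradient magnitude (graylevel/px) for a pixel
#'   to cast votes.
#' @param polarity `"dark"` for dark cells on a brighter background (votes are
#'   cast against the gradient direction) or `"bright"` for the opposite.
#' @param min_distance_px minimum distance between detected centres; defaults
#'   to 1.5x the smallest search radius (two cell bodies cannot overlap that
#'   much).
#' @return object of class `detection_config`.
#' @export
detection_config <- function(radius_range_um = c(4.3, 7.6),
                             resolution = 0.33,
                             sensitivity = 0.25,
                             grad_threshold = 0.05,
                             polarity = c("dark", "bright"),
                             min_distance_px = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(length(radius_range_um) == 2L, radius_range_um[1] > 0,
            radius_range_um[1] < radius_range_um[2], resolution > 0,
            sensitivity > 0, grad_threshold > 0)
  rpx <- radius_range_um / resolution
  if (is.null(min_distance_px)) min_distance_px <- floor(1.5 * rpx[1])
  structure(list(radius_range_um = radius_range_um, resolution = resolution,
                 radius_range_px = rpx, sensitivity = sensitivity,
                 grad_threshold = grad_threshold, polarity = polarity,
                 min_distance_px = min_distance_px),
            class = "detection_config")
}

sobel_gradients <- function(frame) {
  # frame is indexed [row = y, col = x]; krow varies along rows -> d/dy
  # filter2 performs convolution (kernel flipped); the Sobel kernel is
  # antisymmetric, so negate to obtain the true correlation-sense gradient
  krow <- -matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3) / 8
  gy <- EBImage::filter2(frame, krow, boundary = "replicate")
  gx <- EBImage::filter2(frame, t(krow), boundary = "replicate")
  list(gx = gx, gy = gy)
}

gaussian_kernel <- function(sigma) {
  size <- 2L * ceiling(2.5 * sigma) + 1L
  EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
}

#' Detect circular cells in one frame (Circular Hough Transform)
#'
#' Gradient-based CHT: edge pixels above `grad_threshold` cast votes at the
#' candidate centre `p - r * g/|g|` (dark-on-bright polarity) for every radius
#' in the configured range; per-radius accumulators are Gaussian-smoothed, and
#' local maxima of the radius-wise maximum that exceed the sensitivity
#' threshold become detections, with non-maximum suppression at
#' `min_distance_px`. Centres are reported with sub-pixel precision (3x3
#' vote-weighted centroid refinement); radii at integer precision.
#'
#' @param frame numeric H x W matrix, graylevels in `[0, 1]`.
#' @param config a [detection_config()].
#' @return data.frame with columns `x`, `y` (0-based pixel coordinates, `x` =
#'   column), `radius` (px) and `votes`; zero rows when nothing is found.
#' @export
detect_cells <- function(frame, config = detection_config()) {
  stopifnot(is.matrix(frame), inherits(config, "detection_config"))
  H <- nrow(frame); W <- ncol(frame)
  empty <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                      votes = numeric(0))

  sm <- EBImage::filter2(frame, gaussian_kernel(1.5), boundary = "replicate")
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  edge <- which(mag > config$grad_threshold)
  if (length(edge) == 0L) return(empty)

  ey <- ((edge - 1L) %% H) + 1L       # row (1-based)
  ex <- ((edge - 1L) %/% H) + 1L      # col (1-based)
  ux <- g$gx[edge] / mag[edge]
  uy <- g$gy[edge] / mag[edge]
  if (config$polarity == "dark") { ux <- -ux; uy <- -uy }

  radii <- seq(floor(config$radius_range_px[1]), ceiling(config$radius_range_px[2]))
  nr <- length(radii)
  ksm <- gaussian_kernel(3)
  # ray voting: every edge pixel votes at each radius along its gradient ray,
  # so centres of moderately deformed (non-circular) cells still accumulate;
  # the per-radius counts are kept to recover the radius at each peak
  acc <- array(0L, dim = c(H, W, nr))
  for (ri in seq_len(nr)) {
    r <- radii[ri]
    cx <- as.integer(round(ex + r * ux))
    cy <- as.integer(round(ey + r * uy))
    keep <- cx >= 1L & cx <= W & cy >= 1L & cy <= H
    if (!any(keep)) next
    idx <- cy[keep] + (cx[keep] - 1L) * H
    acc[, , ri] <- tabulate(idx, nbins = H * W)
  }
  accsum <- EBImage::filter2(matrix(rowSums(matrix(acc, H * W, nr)), H, W),
                             ksm, boundary = 0)

  # 0.3: net gain of a coherent vote cloud under the sigma = 3 accumulator
  # smoothing, so `sensitivity` reads as the required fraction of a complete
  # circle of voting edge pixels
  rmid <- stats::median(radii)
  thr <- config$sensitivity * 2 * pi * rmid * 0.3
  accmax <- accsum

  # local maxima of accmax within a 5x5 neighbourhood
  ismax <- accmax >= thr
  for (dx in -2:2) for (dy in -2:2) {
    if (dx == 0 && dy == 0) next
    shifted <- matrix(-Inf, H, W)
    ys <- max(1, 1 + dy):min(H, H + dy)
    xs <- max(1, 1 + dx):min(W, W + dx)
    shifted[ys, xs] <- accmax[ys - dy, xs - dx]
    ismax <- ismax & (accmax >= shifted)
  }
  peaks <- which(ismax)
  if (length(peaks) == 0L) return(empty)

  py <- ((peaks - 1L) %% H) + 1L
  px_ <- ((peaks - 1L) %/% H) + 1L
  pv <- accmax[peaks]
  ord <- order(pv, decreasing = TRUE)
  py <- py[ord]; px_ <- px_[ord]; pv <- pv[ord]
  keep <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    kept <- which(keep)
    d2 <- (px_[kept] - px_[i])^2 + (py[kept] - py[i])^2
    keep[i] <- all(d2 >= config$min_distance_px^2)
  }
  py <- py[keep]; px_ <- px_[keep]; pv <- pv[keep]

  # sub-pixel centre: vote-weighted centroid over the 3x3 neighbourhood
  subx <- suby <- numeric(length(py))
  for (i in seq_along(py)) {
    ys <- max(1, py[i] - 1):min(H, py[i] + 1)
    xs <- max(1, px_[i] - 1):min(W, px_[i] + 1)
    wts <- accmax[ys, xs, drop = FALSE]
    subx[i] <- sum(outer(rep(1, length(ys)), xs) * wts) / sum(wts)
    suby[i] <- sum(outer(ys, rep(1, length(xs))) * wts) / sum(wts)
  }
  # radius at each peak: strongest per-radius vote count in a 2-px
  # neighbourhood of the centre
  rad <- numeric(length(py))
  for (i in seq_along(py)) {
    ys <- max(1, py[i] - 2):min(H, py[i] + 2)
    xs <- max(1, px_[i] - 2):min(W, px_[i] + 2)
    per_r <- apply(acc[ys, xs, , drop = FALSE], 3, sum)
    rad[i] <- radii[which.max(per_r)]
  }
  data.frame(x = subx - 1, y = suby - 1, radius = rad, votes = pv)
}

#' Detect cells in every frame of a video
#'
#' @param video a `frame_stack`.
#' @param config a [detection_config()].
#' @return data.frame with columns `frame` (1-based), `x`, `y` (0-based px),
#'   `radius`, `votes`.
#' @export
detect_video <- function(video, config = detection_config()) {
  stopifnot(inherits(video, "frame_stack"))
  out <- lapply(seq_len(dim(video)[3]), function(t) {
    d <- detect_cells(video[, , t], config)
    if (nrow(d)) cbind(frame = t, d) else
      cbind(frame = integer(0), d)
  })
  do.call(rbind, out)
}
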