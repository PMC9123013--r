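#' Preprocessing configuration for ROI sequences
#'
#' Parameters of the luminance-robust four-stage ROI pipeline: inversion,
#' mean-threshold background suppression, Gaussian windowing and adaptive
#' contrast enhancement (histogram stretch of the first frame, histogram
#' matching of the rest).
#'
#' @param roi_size side of the square crop in px (odd).
#' @param sigma_px standard deviation of the Gaussian window, px. The default
#'   18 px is the average radius of the cell-detection search range and
#'   corresponds to about 5.9 um at 0.33 um/px.
#' @param gaussian_peak `"one"` normalises the window to value 1 at the
#'   centre (the cell centre's intensity is preserved); `"unit_integral"`
#'   rescales so the window integrates to 1 (all features scale by a common
#'   constant).
#' @param q_low,q_high quantile levels defining the stretch limits `l1`, `l2`
#'   on the first frame (linear-interpolation quantile estimator).
#' @param hist_bins graylevel bin count for histogram/CDF diagnostics (the
#'   matching map itself is exact on the empirical graylevels).
#' @param border `"replicate"` pads crops that extend beyond the frame with
#'   the nearest edge pixel.
#' @param quantization output of the background-suppression stage is rounded
#'   to this graylevel grid (default 2^-17, well below a 16-bit camera step);
#'   it makes the stage's shift-invariance exact in floating point.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(roi_size = 63L, sigma_px = 18, gaussian_peak = c("one", "unit_integral"),
                              q_low = 0.01, q_high = 0.99, hist_bins = 256L,
                              border = "replicate", quantization = 2^-17) {
  gaussian_peak <- match.arg(gaussian_peak)
  stopifnot(roi_size %% 2L == 1L, roi_size > 0L, sigma_px > 0,
            q_low >= 0, q_low < q_high, q_high <= 1, hist_bins >= 2L,
            identical(border, "replicate"), quantization >= 0)
  structure(list(roi_size = as.integer(roi_size), sigma_px = sigma_px,
                 gaussian_peak = gaussian_peak, q_low = q_low, q_high = q_high,
                 hist_bins = as.integer(hist_bins), border = border,
                 quantization = quantization),
            class = "preprocess_config")
}

roi_stages <- c("raw", "inverted", "suppressed", "windowed", "enhanced")

new_roi_sequence <- function(arr, stage, track_id, frames) {
  stopifnot(length(dim(arr)) == 3L, stage %in% roi_stages)
  structure(arr, stage = stage, track_id = track_id, frames = frames,
            class = c("roi_sequence", "array"))
}

roi_stage <- function(roi) attr(roi, "stage")

advance_stage <- function(roi, arr, to) {
  new_roi_sequence(arr, to, attr(roi, "track_id"), attr(roi, "frames"))
}

#' @export
print.roi_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("roi_sequence: %dx%d px x %d frame(s), stage '%s', track %s\n",
              d[1], d[2], d[3], attr(x, "stage"),
              paste(attr(x, "track_id"), collapse = ",")))
  invisible(x)
}

#' Extract the ROI sequence of one track
#'
#' Crops a fixed-size window centred on the (rounded) detection at every
#' frame of the track. Crops that extend beyond the frame are replicate-
#' padded; padded pixels take the nearest edge value.
#'
#' @param video a `frame_stack`.
#' @param track data.frame with columns `frame`, `x`, `y` (one track's rows
#'   of a `track_set`).
#' @param config a [preprocess_config()].
#' @return a `roi_sequence` at stage `"raw"`: `roi_size` x `roi_size` x T'
#'   array, one crop per track frame, in source-frame order.
#' @export
extract_roi_sequence <- function(video, track, config = preprocess_config()) {
  stopifnot(inherits(video, "frame_stack"), nrow(track) >= 1L)
  H <- dim(video)[1]; W <- dim(video)[2]
  half <- (config$roi_size - 1L) %/% 2L
  ord <- order(track$frame)
  track <- track[ord, ]
  arr <- array(0, dim = c(config$roi_size, config$roi_size, nrow(track)))
  for (i in seq_len(nrow(track))) {
    cx <- round(track$x[i]) + 1L   # 1-based column of the centre pixel
    cy <- round(track$y[i]) + 1L
    rows <- pmin(pmax((cy - half):(cy + half), 1L), H)  # replicate padding
    cols <- pmin(pmax((cx - half):(cx + half), 1L), W)
    arr[, , i] <- video[rows, cols, track$frame[i]]
  }
  tid <- if ("track_id" %in% names(track)) track$track_id[1] else NA_integer_
  new_roi_sequence(arr, "raw", tid, track$frame)
}

#' Invert a raw ROI sequence
#'
#' Brightfield cells are dark objects on a brighter background; the linear
#' map `I = 1 - I_O` turns them into bright objects on a dark background, the
#' polarity every later stage (and the feature backbone) expects.
#'
#' @param roi `roi_sequence` at stage `"raw"`.
#' @return `roi_sequence` at stage `"inverted"`.
#' @export
invert_roi <- function(roi) {
  stopifnot(inherits(roi, "roi_sequence"), roi_stage(roi) == "raw")
  advance_stage(roi, 1 - unclass(roi), "inverted")
}

#' Suppress the background of an inverted ROI sequence
#'
#' Per frame, the mean luminance `m` is computed and the piecewise map
#' `0 if I < m, I - m otherwise` is applied. Adding any constant luminance
#' bias to the input leaves the output unchanged (the mean shifts by the same
#' constant), which is the mechanism that makes downstream classification
#' insensitive to illumination offsets. The output is rounded to the
#' `quantization` graylevel grid so this invariance is exact in floating
#' point.
#'
#' @param roi `roi_sequence` at stage `"inverted"`.
#' @param config a [preprocess_config()].
#' @return `roi_sequence` at stage `"suppressed"`.
#' @export
suppress_background <- function(roi, config = preprocess_config()) {
  stopifnot(inherits(roi, "roi_sequence"), roi_stage(roi) == "inverted")
  arr <- unclass(roi)
  for (t in seq_len(dim(arr)[3])) {
    fr <- arr[, , t]
    m <- mean(fr)
    out <- pmax(fr - m, 0)  # pixels at the mean map to 0 either way
    if (config$quantization > 0) {
      out <- round(out / config$quantization) * config$quantization
    }
    arr[, , t] <- out
  }
  advance_stage(roi, arr, "suppressed")
}

gaussian_window_matrix <- function(size, sigma, peak = "one") {
  half <- (size - 1) / 2
  x <- seq_len(size) - 1 - half
  g <- exp(-x^2 / (2 * sigma^2))
  w <- outer(g, g)
  if (peak == "unit_integral") w <- w / sum(w)
  w
}

#' Apply a Gaussian spatial window to a suppressed ROI sequence
#'
#' Pixelwise multiplication by a centred, separable 2-D Gaussian
#' `G(x, y) = A exp(-x^2 / 2 sigma^2) exp(-y^2 / 2 sigma^2)`; it down-weights
#' the periphery of the crop so neighbouring cells contribute little to the
#' features. With the default peak-1 normalisation the centre pixel is
#' unchanged and a pixel at offset `(sigma, 0)` is attenuated by
#' `exp(-1/2)`.
#'
#' @param roi `roi_sequence` at stage `"suppressed"`.
#' @param config a [preprocess_config()].
#' @return `roi_sequence` at stage `"windowed"`.
#' @export
gaussian_window <- function(roi, config = preprocess_config()) {
  stopifnot(inherits(roi, "roi_sequence"), roi_stage(roi) == "suppressed")
  arr <- unclass(roi)
  w <- gaussian_window_matrix(dim(arr)[1], config$sigma_px, config$gaussian_peak)
  for (t in seq_len(dim(arr)[3])) arr[, , t] <- arr[, , t] * w
  advance_stage(roi, arr, "windowed")
}

stretch_frame <- function(fr, l1, l2) {
  if (l2 - l1 < .Machine$double.eps * 8) {
    # degenerate first frame: no usable graylevel spread
    return(matrix(0, nrow(fr), ncol(fr)))
  }
  out <- (fr - l1) / (l2 - l1)
  pmin(pmax(out, 0), 1)
}

match_histogram <- function(fr, ref, bins = NULL) {
  # exact histogram specification on the empirical graylevels:
  # T(v) = Q_ref(F_src(v)) with the right-continuous empirical CDF and its
  # generalised inverse. Exact under ties (the zero atom left by background
  # suppression maps onto the reference's zero atom) and the identity map
  # when a frame is matched to itself.
  v <- as.vector(fr)
  uv <- sort(unique(v))
  h_src <- tabulate(match(v, uv), length(uv))
  cdf_src <- cumsum(h_src) / length(v)
  # midpoint convention: an atom (tied graylevel, e.g. the suppressed-
  # background zeros) is taken at the middle of its CDF mass, so atoms of
  # slightly different weight in source and reference still map onto each
  # other
  mid_src <- cdf_src - h_src / (2 * length(v))
  ur <- sort(unique(as.vector(ref)))
  cdf_ref <- cumsum(tabulate(match(as.vector(ref), ur), length(ur))) / length(ref)
  idx <- pmin(findInterval(mid_src, cdf_ref, left.open = TRUE) + 1L, length(ur))
  matrix(ur[idx][match(v, uv)], nrow(fr), ncol(fr))
}

#' Contrast-enhance a windowed ROI sequence
#'
#' The first frame is histogram-stretched with the piecewise-linear map that
#' sends the `q_low` quantile graylevel `l1` to 0, the `q_high` quantile `l2`
#' to 1 and is linear in between. Every later frame is histogram-matched to
#' the enhanced first frame, which keeps the sequence's graylevel statistics
#' homogeneous over time.
#'
#' @param roi `roi_sequence` at stage `"windowed"`.
#' @param config a [preprocess_config()].
#' @return `roi_sequence` at stage `"enhanced"`.
#' @export
enhance_sequence <- function(roi, config = preprocess_config()) {
  stopifnot(inherits(roi, "roi_sequence"), roi_stage(roi) == "windowed")
  arr <- unclass(roi)
  first <- arr[, , 1]
  l <- stats::quantile(first, c(config$q_low, config$q_high), names = FALSE,
                       type = 7)
  ref <- stretch_frame(first, l[1], l[2])
  arr[, , 1] <- ref
  if (dim(arr)[3] > 1L) {
    for (t in 2:dim(arr)[3]) {
      arr[, , t] <- match_histogram(arr[, , t], ref, config$hist_bins)
    }
  }
  advance_stage(roi, arr, "enhanced")
}

#' Run the ROI preprocessing pipeline
#'
#' `mode = "background_suppression"` applies the full luminance-robust chain
#' (invert, suppress, window, enhance); `mode = "no_preprocessing"` only
#' inverts, so the object polarity stays constant for the feature backbone
#' but nothing protects against luminance bias.
#'
#' @param roi `roi_sequence` at stage `"raw"`.
#' @param config a [preprocess_config()].
#' @param mode preprocessing arm.
#' @return `roi_sequence` at stage `"enhanced"` (background_suppression) or
#'   `"inverted"` (no_preprocessing).
#' @export
preprocess <- function(roi, config = preprocess_config(),
                       mode = c("background_suppression", "no_preprocessing")) {
  mode <- match.arg(mode)
  stopifnot(inherits(roi, "roi_sequence"), roi_stage(roi) == "raw")
  if (mode == "no_preprocessing") return(invert_roi(roi))
  enhance_sequence(gaussian_window(suppress_background(invert_roi(roi), config),
                                   config), config)
}
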