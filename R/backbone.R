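#' Backbone specification for deep-feature extraction
#'
#' The feature extractor is pluggable. Four published CNN architectures are
#' recognised by name — their pooling-layer dimensionality and input size are
#' part of the contract and can be computed without weights via
#' [backbone_dim()] — and a deterministic, weight-free filter-bank fallback
#' is provided so the whole pipeline runs without any model download.
#'
#' @param name one of `"fallback"`, `"alexnet"`, `"googlenet"`,
#'   `"resnet101"`, `"nasnetlarge"`.
#' @param dim output dimensionality of the fallback backbone. `NULL` (the
#'   default) keeps the filter bank's natural pooled dimensionality, where
#'   each feature is one (filter, grid cell, statistic) triple; any other
#'   value inserts a fixed seeded Gaussian random projection to `dim`
#'   dimensions followed by a ReLU.
#' @param seed integer seed fixing the fallback's random projection (unused
#'   at the natural dimensionality).
#' @param allow_fallback when a named CNN backbone is requested but no
#'   weights are available, `TRUE` silently substitutes the fallback;
#'   `FALSE` (default) raises an explicit error.
#' @return object of class `backbone_spec` with fields `name`, `layer`,
#'   `input_size`, `n_features`, `dim`, `seed`.
#' @export
backbone_spec <- function(name = c("fallback", "alexnet", "googlenet",
                                   "resnet101", "nasnetlarge"),
                          dim = NULL, seed = 17L, allow_fallback = FALSE) {
  name <- match.arg(name)
  if (is.null(dim)) dim <- fallback_dim()
  info <- switch(name,
    fallback    = list(layer = "pool", input_size = 63L, n_features = as.integer(dim)),
    alexnet     = list(layer = "pool5", input_size = 227L, n_features = backbone_dim("alexnet")),
    googlenet   = list(layer = "pool5", input_size = 224L, n_features = backbone_dim("googlenet")),
    resnet101   = list(layer = "pool5", input_size = 224L, n_features = backbone_dim("resnet101")),
    nasnetlarge = list(layer = "average_pooling", input_size = 331L, n_features = backbone_dim("nasnetlarge"))
  )
  structure(c(list(name = name, dim = as.integer(dim), seed = as.integer(seed),
                   allow_fallback = isTRUE(allow_fallback)), info),
            class = "backbone_spec")
}

conv_out <- function(size, kernel, stride = 1L, pad = 0L) {
  (size + 2L * pad - kernel) %/% stride + 1L
}

#' Feature dimensionality of the named backbones, by shape inference
#'
#' Walks the published layer geometry of each architecture (kernel, stride
#' and padding of every convolution/pooling stage, channel arithmetic of the
#' block structure) and returns the flattened size of the transfer-learning
#' layer. No weights are involved: the dimensionality is an architectural
#' constant.
#'
#' * AlexNet `pool5`: 227 -> conv11/4 -> pool3/2 -> conv5(p2) -> pool3/2 ->
#'   3x conv3(p1) -> pool3/2 gives a 6x6 map with 256 channels: 9216.
#' * GoogleNet `pool5`: global average pooling over the inception-5b
#'   concatenation (384 + 384 + 128 + 128 channels): 1024.
#' * ResNet101 `pool5`: global average pooling over the conv5 block,
#'   512 x expansion 4 channels: 2048.
#' * NASNet-Large `average_pooling`: the final normal cell concatenates 6
#'   branch outputs of 672 filters (168 base filters doubled at each of the
#'   two reduction stages): 4032.
#'
#' @param name backbone name.
#' @return integer feature count.
#' @export
backbone_dim <- function(name) {
  switch(name,
    alexnet = {
      s <- 227L
      s <- conv_out(s, 11L, 4L, 0L)   # conv1
      s <- conv_out(s, 3L, 2L, 0L)    # pool1
      s <- conv_out(s, 5L, 1L, 2L)    # conv2
      s <- conv_out(s, 3L, 2L, 0L)    # pool2
      s <- conv_out(s, 3L, 1L, 1L)    # conv3
      s <- conv_out(s, 3L, 1L, 1L)    # conv4
      s <- conv_out(s, 3L, 1L, 1L)    # conv5
      s <- conv_out(s, 3L, 2L, 0L)    # pool5
      256L * s * s
    },
    googlenet = {
      # inception 5b concatenation, then global average pooling
      sum(c(384L, 384L, 128L, 128L))
    },
    resnet101 = {
      # bottleneck expansion 4 on the 512-filter conv5 stage, global avg pool
      512L * 4L
    },
    nasnetlarge = {
      # NASNet-A (6 @ 4032): base cell width 168, doubled at each of the two
      # reduction cells; the normal cell concatenates 6 hidden states
      168L * 2L * 2L * 6L
    },
    stop("unknown backbone: ", name)
  )
}

#' Natural output dimensionality of the fallback filter bank
#'
#' 13 filters (11 zero-sum band-pass/edge kernels + 2 rectified local-
#' luminance kernels) x 3x3 grid cells x 2 pooled statistics.
#'
#' @return integer.
#' @export
fallback_dim <- function() {
  13L * 9L * 2L
}

# Deterministic multi-scale filter bank used by the fallback backbone:
# difference-of-Gaussian (blob) kernels and oriented odd-Gabor (edge) kernels.
fallback_filter_bank <- function() {
  gk <- function(sigma) {
    half <- ceiling(3 * sigma)
    x <- (-half):half
    k <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
    k / sum(k)
  }
  dog <- function(s1, s2) {
    k1 <- gk(s1); k2 <- gk(s2)
    n <- nrow(k2)
    pad <- (n - nrow(k1)) %/% 2
    k1p <- matrix(0, n, n)
    k1p[pad + seq_len(nrow(k1)), pad + seq_len(nrow(k1))] <- k1
    k1p - k2
  }
  gabor_odd <- function(sigma, theta) {
    half <- ceiling(2.5 * sigma)
    x <- (-half):half
    xx <- outer(rep(1, length(x)), x)
    yy <- outer(x, rep(1, length(x)))
    xr <- xx * cos(theta) + yy * sin(theta)
    k <- sin(2 * pi * xr / (4 * sigma)) * exp(-(xx^2 + yy^2) / (2 * sigma^2))
    k / sum(abs(k))
  }
  filters <- list(dog(1, 2), dog(2, 4), dog(4, 8))
  for (s in c(1.5, 3)) for (th in (0:3) * pi / 4) {
    filters[[length(filters) + 1L]] <- gabor_odd(s, th)
  }
  types <- rep("zero_sum", length(filters))
  # rectified local-luminance channels: unit-sum smoothing kernels whose
  # responses pass a ReLU at a fixed threshold. Like a CNN's biased
  # convolution + ReLU, they make the encoding sensitive to absolute
  # luminance, so an un-suppressed constant bias corrupts the features
  filters <- c(filters, list(gk(2), gk(6)))
  types <- c(types, rep("luminance", 2L))
  list(filters = filters, types = types)
}

# 3x3 spatial grid pooling: mean and max per cell of |response| (zero-sum
# band-pass kernels) or of ReLU(response - 0.1) (luminance kernels).
pool_grid <- function(resp, type = "zero_sum", grid = 3L) {
  r <- if (type == "luminance") pmax(resp - 0.1, 0) else abs(resp)
  n <- nrow(r)
  cuts <- floor(seq(0, n, length.out = grid + 1L))
  out <- numeric(2L * grid * grid)
  k <- 0L
  for (i in seq_len(grid)) for (j in seq_len(grid)) {
    blk <- r[(cuts[i] + 1L):cuts[i + 1L], (cuts[j] + 1L):cuts[j + 1L]]
    out[k + 1L] <- mean(blk)
    out[k + 2L] <- max(blk)
    k <- k + 2L
  }
  out
}

fallback_projection <- function(n_raw, dim, seed) {
  # fixed seeded Gaussian random projection; restore the RNG state afterwards
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  matrix(stats::rnorm(dim * n_raw) / sqrt(n_raw), dim, n_raw)
}

#' Extract backbone feature signals from a ROI sequence
#'
#' Every frame of the (preprocessed) ROI sequence is encoded as a feature
#' vector and the vectors are stacked over time into per-feature signals
#' `f_i(t)`. For a named CNN backbone the frame would be bicubically resized
#' to the architecture's input size, replicated to 3 channels and read out at
#' the transfer-learning layer; since no pretrained weights ship with this
#' package, requesting a named backbone raises an error unless
#' `allow_fallback` is set. The fallback backbone is a deterministic filter
#' bank (multi-scale difference-of-Gaussian and oriented odd-Gabor kernels)
#' with 3x3 spatial mean/max pooling of the absolute responses; each output
#' feature is one (filter, grid cell, statistic) triple. When `spec$dim`
#' differs from the natural [fallback_dim()], a fixed seeded Gaussian random
#' projection to `spec$dim` dimensions followed by a ReLU is appended.
#'
#' @param roi a `roi_sequence` (any stage past `"raw"`).
#' @param spec a [backbone_spec()].
#' @return object of class `feature_signals`: list with `signals` (features x
#'   frames matrix), `feature_ids`, `track_id`, `frames`, `backbone`.
#' @export
backbone_features <- function(roi, spec = backbone_spec()) {
  stopifnot(inherits(roi, "roi_sequence"), inherits(spec, "backbone_spec"))
  if (roi_stage(roi) == "raw") {
    stop("preprocess the ROI sequence before feature extraction")
  }
  if (spec$name != "fallback") {
    if (!spec$allow_fallback) {
      stop("pretrained weights for backbone '", spec$name, "' are not ",
           "available in this installation; supply them through a custom ",
           "extractor or use backbone_spec(\"fallback\") / allow_fallback = ",
           "TRUE for the deterministic filter-bank backbone")
    }
    spec <- backbone_spec("fallback", dim = spec$dim, seed = spec$seed)
  }
  arr <- unclass(roi)
  Tn <- dim(arr)[3]
  bank <- fallback_filter_bank()
  n_raw <- fallback_dim()
  project <- spec$dim != n_raw
  proj <- if (project) fallback_projection(n_raw, spec$dim, spec$seed)
  sig <- matrix(0, spec$dim, Tn)
  for (t in seq_len(Tn)) {
    # input rectification at a fixed threshold — the analogue of a biased
    # convolution + ReLU input stage. It makes the encoding sensitive to
    # absolute luminance (as pretrained CNN features are), which is exactly
    # why the background-suppression preprocessing is needed upstream.
    fr <- pmax(arr[, , t] - 0.1, 0)
    raw <- unlist(lapply(seq_along(bank$filters), function(fi) {
      pool_grid(EBImage::filter2(fr, bank$filters[[fi]], boundary = 0),
                bank$types[fi])
    }))
    sig[, t] <- if (project) pmax(proj %*% raw, 0) else raw
  }
  ids <- if (project) {
    paste0("f", seq_len(spec$dim))
  } else {
    stats_ <- c("mean", "max")
    as.vector(sapply(seq_along(bank$filters), function(fi) {
      paste0("flt", fi, ".g", rep(1:9, each = 2), ".", stats_)
    }))
  }
  structure(list(signals = sig,
                 feature_ids = ids,
                 track_id = attr(roi, "track_id"),
                 frames = attr(roi, "frames"),
                 backbone = spec$name),
            class = "feature_signals")
}

#' @export
print.feature_signals <- function(x, ...) {
  cat(sprintf("feature_signals: %d features x %d frames (backbone '%s', track %s)\n",
              nrow(x$signals), ncol(x$signals), x$backbone,
              paste(x$track_id, collapse = ",")))
  invisible(x)
}

#' Temporal dynamics descriptor of feature signals
#'
#' Summarises each feature signal `f_i(t)` by its sample standard deviation
#' over time — the track's morphodynamic signature. Features that are zero
#' for the entire sequence carry no information (they correspond to image
#' regions with no activity) and are dropped; the mask of dropped features is
#' recorded.
#'
#' @param signals a `feature_signals` object.
#' @param type `"sd"` (sample standard deviation, default) or `"cv"`
#'   (coefficient of variation, sd/|mean|).
#' @return named numeric vector (one entry per retained feature) with
#'   attributes `zero_mask` (logical, length = all features), `track_id` and
#'   `statistic`.
#' @export
dynamics_descriptor <- function(signals, type = c("sd", "cv")) {
  type <- match.arg(type)
  stopifnot(inherits(signals, "feature_signals"))
  if (ncol(signals$signals) < 2L) {
    stop("dynamics are undefined for a single-frame track")
  }
  zero <- apply(signals$signals == 0, 1, all)
  kept <- signals$signals[!zero, , drop = FALSE]
  s <- apply(kept, 1, stats::sd)
  if (type == "cv") {
    m <- abs(rowMeans(kept))
    s <- ifelse(m > 0, s / m, 0)
  }
  names(s) <- signals$feature_ids[!zero]
  structure(s, zero_mask = zero, track_id = signals$track_id, statistic = type)
}
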