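#' Simulation configuration for synthetic label-free time-lapse videos
#'
#' Defines the study conditions of a simulated brightfield acquisition: dark,
#' shape-fluctuating cells arranged in persistent spatial clusters, drifting
#' over a brighter background, sampled at a fixed frame interval and spatial
#' resolution. Classes differ only through the per-class morphodynamic
#' parameters, so any downstream discrimination must come from those.
#'
#' @param image_size integer vector `c(height, width)` in pixels.
#' @param n_frames number of frames.
#' @param frame_interval minutes between frames.
#' @param resolution spatial calibration in micrometres per pixel.
#' @param class_params list with one entry per class; each entry is a list
#'   with elements `radius_mean` (um), `radius_sd` (um), `speed` (um/min),
#'   `fluctuation_amplitude` (dimensionless boundary-perturbation scale) and
#'   `fluctuation_rate` (1/min). Missing elements fall back to the defaults
#'   (radius 5.9 +/- 0.5 um, speed 0.2 um/min, amplitude 0.15, rate 0.2).
#' @param n_clusters number of spatial clusters per video.
#' @param cells_per_cluster cells seeded in each cluster.
#' @param intra_cluster_spacing typical distance between neighbouring cells of
#'   a cluster, in micrometres.
#' @param inter_cluster_spacing minimum distance between cluster centres, um.
#' @param background_level background graylevel in `[0, 1]`.
#' @param cell_contrast how much darker than the background a cell centre is.
#' @param noise_sd additive Gaussian camera noise, graylevels.
#' @param seed integer seed; the same seed gives a bit-identical video and
#'   ground truth.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(image_size = c(512L, 512L),
                              n_frames = 60L,
                              frame_interval = 1,
                              resolution = 0.33,
                              class_params = list(list(), list()),
                              n_clusters = 4L,
                              cells_per_cluster = 5L,
                              intra_cluster_spacing = 15,
                              inter_cluster_spacing = 80,
                              background_level = 0.75,
                              cell_contrast = 0.35,
                              noise_sd = 0.02,
                              seed = 1L) {
  defaults <- list(radius_mean = 5.9, radius_sd = 0.5, speed = 0.2,
                   fluctuation_amplitude = 0.15, fluctuation_rate = 0.2)
  class_params <- lapply(class_params, function(p) utils::modifyList(defaults, p))
  cfg <- list(
    image_size = as.integer(image_size), n_frames = as.integer(n_frames),
    frame_interval = frame_interval, resolution = resolution,
    n_classes = length(class_params), class_params = class_params,
    n_clusters = as.integer(n_clusters),
    cells_per_cluster = as.integer(cells_per_cluster),
    intra_cluster_spacing = intra_cluster_spacing,
    inter_cluster_spacing = inter_cluster_spacing,
    background_level = background_level, cell_contrast = cell_contrast,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  stopifnot(
    length(cfg$image_size) == 2L, all(cfg$image_size > 0L),
    cfg$n_frames >= 1L, cfg$frame_interval > 0, cfg$resolution > 0,
    cfg$n_classes >= 1L, cfg$n_clusters >= 1L, cfg$cells_per_cluster >= 1L,
    cfg$intra_cluster_spacing > 0, cfg$inter_cluster_spacing > 0,
    cfg$noise_sd >= 0, cfg$cell_contrast > 0
  )
  for (p in cfg$class_params) {
    stopifnot(p$radius_mean > 0, p$radius_sd >= 0, p$speed >= 0,
              p$fluctuation_amplitude >= 0, p$fluctuation_rate >= 0)
  }
  if (cfg$background_level - 3 * cfg$noise_sd < 0 ||
      cfg$background_level + 3 * cfg$noise_sd > 1) {
    stop("background_level +/- 3 * noise_sd must stay within [0, 1]")
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: %dx%d px, %d frames @ %g min, %g um/px\n",
              x$image_size[1], x$image_size[2], x$n_frames,
              x$frame_interval, x$resolution))
  cat(sprintf("  %d class(es), %d cluster(s) x %d cells\n",
              x$n_classes, x$n_clusters, x$cells_per_cluster))
  invisible(x)
}

# Ornstein-Uhlenbeck step with unit stationary variance.
ou_step <- function(x, rate) {
  lambda <- min(max(rate, 0), 1)
  (1 - lambda) * x + sqrt(lambda * (2 - lambda)) * stats::rnorm(length(x))
}

#' Generate a synthetic time-lapse video with ground truth
#'
#' Renders `n_frames` frames of dark, boundary-fluctuating cells on a brighter
#' background. Cells are tethered to their cluster centroid by an
#' Ornstein-Uhlenbeck random walk so clusters persist over the whole video,
#' and each cell's boundary radius is modulated by low-order angular harmonics
#' whose coefficients follow an OU process at the class `fluctuation_rate`,
#' scaled by the class `fluctuation_amplitude`.
#'
#' @param config a [simulation_config()].
#' @param class_of_video optional single class index: render all cells with
#'   that class's parameters (one experimental condition per video, as in a
#'   live acquisition). By default cluster `k` gets class
#'   `((k - 1) %% n_classes) + 1` so one video can carry several classes.
#' @return list with `video` (a `frame_stack`: H x W x T array in `[0, 1]`
#'   with calibration attributes) and `truth` (data.frame with columns
#'   `cell_id`, `frame`, `x_px`, `y_px`, `radius_px`, `area_px2` (closed-form
#'   area of the perturbed boundary), `class_label`, `cluster_id`; pixel
#'   coordinates are 0-based, `x` is the column index, frames are 1-based).
#' @export
generate_video <- function(config, class_of_video = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  H <- config$image_size[1]; W <- config$image_size[2]
  Tn <- config$n_frames
  px <- function(um) um / config$resolution

  # --- cluster layout -------------------------------------------------------
  min_sep <- px(config$inter_cluster_spacing)
  r_mean_max <- max(vapply(config$class_params, function(p) px(p$radius_mean), 0))
  spacing_px <- max(px(config$intra_cluster_spacing), 2.2 * r_mean_max)
  # radius a cluster of cells_per_cluster cells needs at this packing
  # density; never below the minimum two-cell separation so small clusters
  # remain placeable
  cluster_radius <- max(spacing_px * sqrt(config$cells_per_cluster / pi),
                        2.6 * r_mean_max)
  margin <- cluster_radius + r_mean_max + 3
  if (margin * 2 >= W || margin * 2 >= H) {
    stop("image too small for the requested cluster layout")
  }
  # jittered grid: cluster centres on a square lattice at >= min_sep spacing
  innerW <- W - 2 * margin
  innerH <- H - 2 * margin
  gx <- floor(innerW / min_sep) + 1L
  gy <- floor(innerH / min_sep) + 1L
  if (gx * gy < config$n_clusters) {
    stop("cell density too high: could not place ", config$n_clusters,
         " clusters with inter_cluster_spacing ", config$inter_cluster_spacing,
         " um in a ", W, "x", H, " px field")
  }
  grid <- as.matrix(expand.grid(
    x = margin + (if (gx > 1L) (seq_len(gx) - 1L) * innerW / (gx - 1L) else innerW / 2),
    y = margin + (if (gy > 1L) (seq_len(gy) - 1L) * innerH / (gy - 1L) else innerH / 2)
  ))
  pick <- sample.int(nrow(grid), config$n_clusters)
  jit <- matrix(stats::runif(2 * config$n_clusters, -0.04, 0.04) * min_sep,
                ncol = 2)
  centers <- grid[pick, , drop = FALSE] + jit

  # --- per-cell initial states ---------------------------------------------
  n_cells <- config$n_clusters * config$cells_per_cluster
  cells <- vector("list", n_cells)
  id <- 0L
  for (k in seq_len(config$n_clusters)) {
    cls <- if (is.null(class_of_video)) ((k - 1L) %% config$n_classes) + 1L else as.integer(class_of_video)
    par <- config$class_params[[cls]]
    r_mean_px <- px(par$radius_mean)
    for (j in seq_len(config$cells_per_cluster)) {
      id <- id + 1L
      placed <- FALSE
      for (attempt in seq_len(4000L)) {
        if (j == 1L) {
          pos <- centers[k, ] + stats::rnorm(2, 0, 1)
        } else {
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- cluster_radius * sqrt(stats::runif(1))
          pos <- centers[k, ] + rad * c(cos(ang), sin(ang))
        }
        ok <- pos[1] > r_mean_px + 2 && pos[1] < W - r_mean_px - 3 &&
          pos[2] > r_mean_px + 2 && pos[2] < H - r_mean_px - 3
        if (ok && j > 1L) {
          prev <- t(vapply(cells[(id - j + 1L):(id - 1L)], function(c.) c.$anchor, numeric(2)))
          ok <- all(sqrt(rowSums((prev - matrix(pos, j - 1L, 2, byrow = TRUE))^2)) >= 2.4 * r_mean_px)
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) {
        stop("cell density too high: could not place ", config$cells_per_cluster,
             " cells per cluster at intra_cluster_spacing ",
             config$intra_cluster_spacing, " um")
      }
      r0 <- max(0.5, stats::rnorm(1, par$radius_mean, par$radius_sd))
      cells[[id]] <- list(
        cluster = k, class = cls, anchor = pos, pos = pos,
        r0 = px(r0),
        eta = stats::rnorm(2),            # harmonic amplitude states (k = 2, 3)
        phase = stats::runif(2, 0, 2 * pi),
        tex_phase = stats::runif(2, 0, 2 * pi),
        par = par
      )
    }
  }

  # --- simulate trajectories and render ------------------------------------
  video <- array(config$background_level, dim = c(H, W, Tn))
  truth <- vector("list", n_cells * Tn)
  row_i <- 0L
  xs <- seq_len(W) - 1  # 0-based pixel-centre coordinates
  ys <- seq_len(H) - 1
  tether <- 0.05

  for (t in seq_len(Tn)) {
    frame <- matrix(config$background_level, H, W)
    depth <- matrix(0, H, W)  # accumulated darkening, max over cells
    for (i in seq_len(n_cells)) {
      cl <- cells[[i]]
      par <- cl$par
      if (t > 1L) {
        step_sd <- px(par$speed * config$frame_interval)
        cl$pos <- cl$pos + tether * (cl$anchor - cl$pos) + step_sd * stats::rnorm(2)
        cl$pos <- pmin(pmax(cl$pos, 2), c(W, H) - 3)
        lam <- par$fluctuation_rate * config$frame_interval
        cl$eta <- ou_step(cl$eta, lam)
        cells[[i]] <- cl
      }
      # render: local window around the cell
      rmax <- cl$r0 * (1 + par$fluctuation_amplitude * 1.5) + 2
      x0 <- max(1L, floor(cl$pos[1] - rmax) + 1L); x1 <- min(W, ceiling(cl$pos[1] + rmax) + 1L)
      y0 <- max(1L, floor(cl$pos[2] - rmax) + 1L); y1 <- min(H, ceiling(cl$pos[2] + rmax) + 1L)
      if (x0 > x1 || y0 > y1) next
      lx <- xs[x0:x1] - cl$pos[1]
      ly <- ys[y0:y1] - cl$pos[2]
      dx <- matrix(lx, length(ly), length(lx), byrow = TRUE)
      dy <- matrix(ly, length(ly), length(lx))
      d <- sqrt(dx^2 + dy^2)
      theta <- atan2(dy, dx)
      amp <- 0.5 * par$fluctuation_amplitude
      Rb <- cl$r0 * (1 + amp * (cl$eta[1] * cos(2 * theta + cl$phase[1]) +
                                cl$eta[2] * cos(3 * theta + cl$phase[2])))
      Rb <- pmax(Rb, 0.3 * cl$r0)
      cover <- pmin(pmax(Rb - d + 0.5, 0), 1)  # anti-aliased fill
      # slight static internal texture so cells are not flat discs
      tex <- 1 + 0.12 * sin(2 * pi * (dx / (1.3 * cl$r0)) + cl$tex_phase[1]) *
                    sin(2 * pi * (dy / (1.3 * cl$r0)) + cl$tex_phase[2])
      dpatch <- config$cell_contrast * cover * tex
      depth[y0:y1, x0:x1] <- pmax(depth[y0:y1, x0:x1], dpatch)

      row_i <- row_i + 1L
      # analytic area of the perturbed boundary R(theta) = r0 (1 + c2 cos(2t+p2)
      # + c3 cos(3t+p3)): A = pi r0^2 (1 + (c2^2 + c3^2) / 2)
      c23 <- amp * cl$eta
      truth[[row_i]] <- c(i, t, cl$pos[1], cl$pos[2], cl$r0,
                          pi * cl$r0^2 * (1 + sum(c23^2) / 2),
                          cl$class, cl$cluster)
    }
    frame <- frame - depth
    if (config$noise_sd > 0) {
      frame <- frame + matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W)
    }
    video[, , t] <- pmin(pmax(frame, 0), 1)
  }

  truth <- as.data.frame(do.call(rbind, truth[seq_len(row_i)]))
  names(truth) <- c("cell_id", "frame", "x_px", "y_px", "radius_px",
                    "area_px2", "class_label", "cluster_id")
  truth$cell_id <- as.integer(truth$cell_id)
  truth$frame <- as.integer(truth$frame)
  truth$class_label <- as.integer(truth$class_label)
  truth$cluster_id <- as.integer(truth$cluster_id)

  video <- frame_stack(video, resolution = config$resolution,
                       frame_interval = config$frame_interval)
  list(video = video, truth = truth)
}

#' Construct a frame stack
#'
#' A `frame_stack` is an H x W x T numeric array of graylevels in `[0, 1]`
#' carrying the physical calibration of the acquisition.
#'
#' @param x numeric array, H x W x T (a single H x W matrix is promoted to one
#'   frame).
#' @param resolution micrometres per pixel.
#' @param frame_interval minutes per frame.
#' @return `frame_stack` array.
#' @export
frame_stack <- function(x, resolution = 0.33, frame_interval = 1) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  structure(x, resolution = resolution, frame_interval = frame_interval,
            class = c("frame_stack", "array"))
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("frame_stack: %d x %d px, %d frame(s), %g um/px, %g min/frame\n",
              d[1], d[2], d[3], attr(x, "resolution"), attr(x, "frame_interval")))
  invisible(x)
}

#' Add a constant luminance bias to images
#'
#' Adds a fixed graylevel offset to every pixel, emulating a macroscopic
#' illumination change between acquisitions. Used by the bias-sensitivity
#' protocol, where increasing biases are applied to test ROIs only.
#'
#' @param x a `frame_stack`, `roi_sequence`, or plain numeric array/matrix.
#' @param bias nonnegative graylevel offset (0.3 corresponds to 30% of the
#'   dynamic range).
#' @param clip clamp the result to `[0, 1]`? Default `FALSE` so that the
#'   additive-composition property `inject_bias(inject_bias(x, a), b) ==
#'   inject_bias(x, a + b)` holds exactly.
#' @return object of the same class as `x`; attribute `bias` accumulates the
#'   total injected offset.
#' @export
inject_bias <- function(x, bias, clip = FALSE) {
  stopifnot(is.numeric(bias), length(bias) == 1L, bias >= 0)
  old <- attributes(x)
  y <- unclass(x) + bias
  if (clip) y <- pmin(pmax(y, 0), 1)
  attributes(y) <- old
  attr(y, "bias") <- (if (is.null(old$bias)) 0 else old$bias) + bias
  y
}

#' Write a frame stack as a multi-page grayscale TIFF
#'
#' One 32-bit float page per frame, values in `[0, 1]`.
#'
#' @param video a `frame_stack`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(video, path) {
  stopifnot(inherits(video, "frame_stack"))
  pages <- lapply(seq_len(dim(video)[3]), function(t) video[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a frame stack
#'
#' @param path TIFF file.
#' @param resolution micrometres per pixel to attach.
#' @param frame_interval minutes per frame to attach.
#' @return `frame_stack`.
#' @export
read_video_tiff <- function(path, resolution = 0.33, frame_interval = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  frame_stack(arr, resolution = resolution, frame_interval = frame_interval)
}

#' Write a ground-truth (or tracking) table as CSV
#'
#' Pixel coordinates in these tables are 0-based; `x` is the column index and
#' `y` the row index; frames are 1-based.
#'
#' @param truth data.frame as returned by [generate_video()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
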