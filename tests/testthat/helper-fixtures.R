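# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; sizes are kept small so the whole suite runs in minutes.

# brute-force assignment oracle: minimum total cost over all injections
brute_assignment_cost <- function(a) {
  n <- nrow(a); m <- ncol(a)
  if (n > m) return(brute_assignment_cost(t(a)))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in perms(cols)) {
      best <- min(best, sum(a[cbind(seq_len(n), p)]))
    }
  }
  best
}

# exhaustive pair-counting AUC oracle (positive = second factor level)
brute_auc <- function(values, labels) {
  labels <- droplevels(as.factor(labels))
  pos <- values[labels == levels(labels)[2L]]
  neg <- values[labels == levels(labels)[1L]]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# a small single-cell static scene
static_scene <- function(seed = 3) {
  generate_video(simulation_config(
    image_size = c(160L, 160L), n_frames = 5L, n_clusters = 1L,
    cells_per_cluster = 1L,
    class_params = list(list(speed = 0, fluctuation_amplitude = 0,
                             radius_sd = 0)),
    noise_sd = 0.02, seed = seed))
}

# raw ROI sequences + metadata from a compact two-class acquisition, cached
# for the whole test session (detection is the slow stage)
local_experiment_cache <- new.env()
small_experiment <- function() {
  if (is.null(local_experiment_cache$exp)) {
    local_experiment_cache$exp <- run_synthetic_experiment(
      n_videos_per_class = 1L, n_clusters = 4L, cells_per_cluster = 3L,
      n_frames = 30L, image_size = c(512L, 512L), seed = 7L,
      use_truth_tracks = TRUE)
  }
  local_experiment_cache$exp
}

# random raw ROI sequence with the stated bias headroom
random_roi <- function(frames = 6L, seed = 1L, max_level = 0.5) {
  set.seed(seed)
  arr <- array(stats::runif(63 * 63 * frames, 0.05, max_level),
               dim = c(63, 63, frames))
  morphodyn:::new_roi_sequence(arr, "raw", 1L, seq_len(frames))
}

# toy linearly separable descriptor set with clusters on both sides
toy_descriptors <- function(n_per_class = 16L, p = 30L, shift = 3,
                            seed = 42L) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * p), n_per_class),
             matrix(stats::rnorm(n_per_class * p, mean = shift), n_per_class))
  n <- 2L * n_per_class
  # 4 clusters per class, alternating sides of a 512-px frame
  cluster <- rep(rep(1:4, each = n_per_class / 4L), 2)
  meta <- data.frame(
    track_id = paste0("t", seq_len(n)),
    video = rep(c("v1", "v2"), each = n_per_class),
    cluster_id = cluster,
    label = rep(c("A", "B"), each = n_per_class),
    centroid_x = ifelse(cluster %% 2 == 0, 100, 400),
    midline = 256)
  track_descriptors(x, meta)
}
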