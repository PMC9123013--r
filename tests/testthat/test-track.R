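test_that("a drifting detection forms a single track", {
  det <- data.frame(frame = 1:3, x = c(0, 2, 4), y = 0, radius = 15)
  tr <- link_tracks(det, max_link_distance = 10, min_length = 1)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$x[order(tr$frame)], c(0, 2, 4))
})

test_that("gaps up to max_gap are bridged with interpolated positions", {
  det <- data.frame(frame = c(1, 2, 5, 6), x = c(0, 1, 4, 5), y = 0,
                    radius = 15)
  tr <- link_tracks(det, max_link_distance = 10, max_gap = 2, min_length = 1)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 6L)
  gaps <- tr[tr$gap, ]
  expect_equal(gaps$frame, c(3, 4))
  expect_equal(gaps$x, c(2, 3))
})

test_that("tracks missing beyond max_gap are closed", {
  det <- data.frame(frame = c(1, 2, 6, 7), x = c(0, 1, 1, 2), y = 0,
                    radius = 15)
  tr <- link_tracks(det, max_link_distance = 10, max_gap = 2, min_length = 1)
  expect_equal(length(unique(tr$track_id)), 2L)
})

test_that("detections beyond the gating radius start new tracks", {
  det <- data.frame(frame = 1:2, x = c(0, 100), y = 0, radius = 15)
  tr <- link_tracks(det, max_link_distance = 10, min_length = 1)
  expect_equal(length(unique(tr$track_id)), 2L)
})

test_that("clusters are connected components of close centroids", {
  # two groups of 3 tracks: intra-group spread ~10 px, groups 300 px apart
  mk <- function(id, cx) data.frame(track_id = id, frame = 1:3,
                                    x = cx + c(0, 5, 10), y = 0, radius = 15,
                                    gap = FALSE, cluster_id = NA_integer_)
  tracks <- do.call(rbind, list(mk(1, 0), mk(2, 10), mk(3, 20),
                                mk(4, 300), mk(5, 310), mk(6, 320)))
  class(tracks) <- c("track_set", "data.frame")
  out <- identify_clusters(tracks, threshold = 50)
  cl <- attr(out, "clusters")
  expect_equal(length(unique(cl$cluster_id)), 2L)
  expect_equal(unname(table(cl$cluster_id)), c(3L, 3L), ignore_attr = TRUE)
  expect_equal(length(unique(cl$cluster_id[cl$track_id <= 3])), 1L)

  # singleton
  single <- mk(1, 0); class(single) <- c("track_set", "data.frame")
  expect_equal(attr(identify_clusters(single, 50), "clusters")$cluster_id, 1L)

  # threshold below every pairwise distance: all singletons
  out2 <- identify_clusters(tracks, threshold = 2)
  expect_equal(length(unique(attr(out2, "clusters")$cluster_id)), 6L)
})

test_that("cluster labels are invariant to track input order", {
  set.seed(8)
  mk <- function(id, cx, cy) data.frame(track_id = id, frame = 1:2,
                                        x = cx + rnorm(2), y = cy + rnorm(2),
                                        radius = 15, gap = FALSE,
                                        cluster_id = NA_integer_)
  tracks <- do.call(rbind, lapply(1:8, function(i) {
    mk(i, 100 * ((i - 1) %% 4), 200 * ((i - 1) %/% 4))
  }))
  class(tracks) <- c("track_set", "data.frame")
  a <- attr(identify_clusters(tracks, threshold = 120), "clusters")
  shuffled <- tracks[sample(nrow(tracks)), ]
  class(shuffled) <- c("track_set", "data.frame")
  b <- attr(identify_clusters(shuffled, threshold = 120), "clusters")
  b <- b[match(a$track_id, b$track_id), ]
  expect_equal(a$cluster_id, b$cluster_id)
})

test_that("trajectories are recovered as single tracks on a sparse scene", {
  g <- generate_video(simulation_config(
    image_size = c(512L, 512L), n_frames = 25L, n_clusters = 4L,
    cells_per_cluster = 2L, intra_cluster_spacing = 22,
    inter_cluster_spacing = 90, seed = 5L))
  det <- detect_video(g$video)
  tr <- link_tracks(det, min_length = 10)
  mt <- match_tracks_to_truth(tr, g$truth)
  full <- mt[!is.na(mt$cell_id) & mt$coverage >= 0.9, ]
  recovered <- sum(table(full$cell_id) == 1)
  expect_gte(recovered / length(unique(g$truth$cell_id)), 0.95)
})

test_that("track CSV round-trip preserves coordinates and clusters", {
  det <- data.frame(frame = 1:12, x = seq(0, 22, 2), y = 5, radius = 15)
  tr <- identify_clusters(link_tracks(det, max_link_distance = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(tr, path)
  back <- read_tracks_csv(path)
  expect_equal(back$x, tr$x)
  expect_equal(back$cluster_id, tr$cluster_id)
})
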