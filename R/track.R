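#' Link per-frame detections into single-cell tracks
#'
#' Frame-to-frame data association by minimum-cost assignment: for every
#' consecutive frame the squared Euclidean distances between active track
#' heads and new detections form the cost matrix, gated at
#' `max_link_distance`, and the Munkres algorithm ([solve_assignment()])
#' finds the globally cheapest pairing. Unassigned detections open new
#' tracks; tracks missing for more than `max_gap` consecutive frames are
#' closed. Positions inside short gaps are filled by linear interpolation and
#' flagged.
#'
#' @param detections data.frame with columns `frame` (1-based), `x`, `y`
#'   (0-based px) and `radius`, as returned by [detect_video()].
#' @param max_link_distance gating radius in px: links longer than this are
#'   forbidden. Default 2x the mean detected radius.
#' @param max_gap maximum number of consecutive missed frames bridged within
#'   a track.
#' @param min_length tracks spanning fewer frames are discarded: temporal
#'   dynamics statistics on very short signals are meaningless.
#' @param n_frames total frames in the video (defaults to `max(frame)`).
#' @return a `track_set`: data.frame with columns `track_id`, `frame`, `x`,
#'   `y`, `radius`, `gap` (TRUE for interpolated gap positions), `cluster_id`
#'   (NA until [identify_clusters()] is applied).
#' @export
link_tracks <- function(detections, max_link_distance = NULL, max_gap = 2L,
                        min_length = 10L, n_frames = NULL) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x", "y", "radius") %in% names(detections)))
  if (nrow(detections) == 0L) {
    return(empty_track_set())
  }
  if (is.null(max_link_distance)) {
    max_link_distance <- 2 * mean(detections$radius)
  }
  if (is.null(n_frames)) n_frames <- max(detections$frame)
  gate2 <- max_link_distance^2
  bigM <- gate2 * 1e6

  tracks <- list()   # each: list(rows = data.frame, last_seen, active)
  active <- integer(0)

  for (t in seq_len(n_frames)) {
    det <- detections[detections$frame == t, , drop = FALSE]
    nd <- nrow(det)
    na_ <- length(active)

    assigned_det <- rep(FALSE, nd)
    matched_tracks <- integer(0)
    if (na_ > 0L && nd > 0L) {
      heads <- t(vapply(tracks[active], function(tr) {
        last <- tr$rows[nrow(tr$rows), ]
        c(last$x, last$y)
      }, numeric(2)))
      cost <- outer(heads[, 1], det$x, "-")^2 + outer(heads[, 2], det$y, "-")^2
      cost[cost > gate2] <- bigM
      # pad to square so tracks/detections may stay unassigned at gate cost
      n <- max(na_, nd)
      pad <- matrix(gate2, n, n)
      pad[seq_len(na_), seq_len(nd)] <- cost
      sol <- solve_assignment(pad)
      for (i in seq_len(na_)) {
        j <- sol$assignment[i]
        if (is.na(j) || j > nd) next
        if (pad[i, j] >= gate2) next   # dummy or gated: no link
        tr_idx <- active[i]
        tr <- tracks[[tr_idx]]
        gap_len <- t - tr$last_seen - 1L
        if (gap_len > 0L) {
          # linear interpolation across the gap, flagged
          last <- tr$rows[nrow(tr$rows), ]
          for (g in seq_len(gap_len)) {
            w <- g / (gap_len + 1L)
            tr$rows <- rbind(tr$rows, data.frame(
              frame = tr$last_seen + g,
              x = last$x + w * (det$x[j] - last$x),
              y = last$y + w * (det$y[j] - last$y),
              radius = last$radius + w * (det$radius[j] - last$radius),
              gap = TRUE))
          }
        }
        tr$rows <- rbind(tr$rows, data.frame(frame = t, x = det$x[j],
                                             y = det$y[j],
                                             radius = det$radius[j],
                                             gap = FALSE))
        tr$last_seen <- t
        tracks[[tr_idx]] <- tr
        assigned_det[j] <- TRUE
        matched_tracks <- c(matched_tracks, tr_idx)
      }
    }
    # close tracks that have been missing for too long
    still_active <- vapply(active, function(k) {
      t - tracks[[k]]$last_seen <= max_gap
    }, logical(1))
    active <- active[still_active]
    # open new tracks for unassigned detections
    if (nd > 0L) {
      for (j in which(!assigned_det)) {
        tracks[[length(tracks) + 1L]] <- list(
          rows = data.frame(frame = t, x = det$x[j], y = det$y[j],
                            radius = det$radius[j], gap = FALSE),
          last_seen = t)
        active <- c(active, length(tracks))
      }
    }
  }

  keep <- vapply(tracks, function(tr) nrow(tr$rows) >= min_length, logical(1))
  tracks <- tracks[keep]
  if (length(tracks) == 0L) return(empty_track_set())
  out <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    cbind(track_id = i, tracks[[i]]$rows)
  }))
  out$cluster_id <- NA_integer_
  class(out) <- c("track_set", "data.frame")
  out
}

empty_track_set <- function() {
  out <- data.frame(track_id = integer(0), frame = integer(0), x = numeric(0),
                    y = numeric(0), radius = numeric(0), gap = logical(0),
                    cluster_id = integer(0))
  class(out) <- c("track_set", "data.frame")
  out
}

#' Time-averaged centroid of each track
#'
#' @param tracks a `track_set`.
#' @return data.frame with `track_id`, `x`, `y` (0-based px) and `n_frames`.
#' @export
track_centroids <- function(tracks) {
  stopifnot(is.data.frame(tracks))
  ids <- sort(unique(tracks$track_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    sub <- tracks[tracks$track_id == id, ]
    data.frame(track_id = id, x = mean(sub$x), y = mean(sub$y),
               n_frames = nrow(sub))
  }))
  out
}

#' Group tracks into spatial clusters
#'
#' Single-linkage connected components: two tracks belong to the same cluster
#' when their time-averaged centroids are closer than `threshold`, directly
#' or through a chain of such links. The labelling is canonical (clusters are
#' numbered by their smallest member `track_id`) and therefore invariant to
#' the order of the input rows.
#'
#' @param tracks a `track_set`.
#' @param threshold linkage distance in px; default 4x the mean detected
#'   radius (twice the mean cell diameter).
#' @return the `track_set` with `cluster_id` filled in; the map is also
#'   attached as attribute `"clusters"` (data.frame `track_id`, `cluster_id`)
#'   together with `"threshold"`.
#' @export
identify_clusters <- function(tracks, threshold = NULL) {
  stopifnot(is.data.frame(tracks), nrow(tracks) > 0L)
  if (is.null(threshold)) threshold <- 4 * mean(tracks$radius)
  cen <- track_centroids(tracks)
  n <- nrow(cen)
  # union-find over centroid-distance edges
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    d <- as.matrix(stats::dist(cen[, c("x", "y")]))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (d[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # canonical labels: clusters ordered by their smallest track_id
  comp_min_id <- tapply(cen$track_id, root, min)
  lab <- match(comp_min_id[as.character(root)], sort(unname(comp_min_id)))
  clusters <- data.frame(track_id = cen$track_id, cluster_id = as.integer(lab))
  tracks$cluster_id <- clusters$cluster_id[match(tracks$track_id, clusters$track_id)]
  attr(tracks, "clusters") <- clusters
  attr(tracks, "threshold") <- threshold
  tracks
}

#' Match recovered tracks to ground-truth trajectories
#'
#' Utility for validating the tracker on synthetic videos: a track is matched
#' to the truth cell whose positions it follows most closely over the frames
#' both cover.
#'
#' @param tracks a `track_set`.
#' @param truth ground-truth table from [generate_video()].
#' @param max_mean_error px; a match requires mean per-frame error below this.
#' @return data.frame `track_id`, `cell_id`, `mean_error`, `coverage`
#'   (fraction of the truth trajectory covered by the track).
#' @export
match_tracks_to_truth <- function(tracks, truth, max_mean_error = 5) {
  ids <- sort(unique(tracks$track_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    sub <- tracks[tracks$track_id == id, ]
    errs <- vapply(split(truth, truth$cell_id), function(tt) {
      common <- intersect(sub$frame, tt$frame)
      if (length(common) < 2L) return(Inf)
      a <- sub[match(common, sub$frame), ]
      b <- tt[match(common, tt$frame), ]
      mean(sqrt((a$x - b$x_px)^2 + (a$y - b$y_px)^2))
    }, numeric(1))
    best <- which.min(errs)
    cell <- as.integer(names(errs)[best])
    cov <- length(intersect(sub$frame, truth$frame[truth$cell_id == cell])) /
      sum(truth$cell_id == cell)
    data.frame(track_id = id,
               cell_id = if (is.finite(errs[best]) && errs[best] <= max_mean_error) cell else NA_integer_,
               mean_error = unname(errs[best]), coverage = cov)
  }))
  out
}

#' Write a track table as CSV
#'
#' Columns `track_id, frame, x_px, y_px, radius_px, gap, cluster_id`; pixel
#' coordinates 0-based (`x` = column), frames 1-based.
#'
#' @param tracks a `track_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  out <- data.frame(track_id = tracks$track_id, frame = tracks$frame,
                    x_px = tracks$x, y_px = tracks$y,
                    radius_px = tracks$radius, gap = tracks$gap,
                    cluster_id = tracks$cluster_id)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a track table written by [write_tracks_csv()]
#'
#' @param path CSV file.
#' @return a `track_set`.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- data.frame(track_id = df$track_id, frame = df$frame, x = df$x_px,
                    y = df$y_px, radius = df$radius_px,
                    gap = if ("gap" %in% names(df)) df$gap else FALSE,
                    cluster_id = if ("cluster_id" %in% names(df)) df$cluster_id else NA_integer_)
  class(out) <- c("track_set", "data.frame")
  out
}
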