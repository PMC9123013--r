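#' Run a seeded synthetic two-arm (or multi-arm) experiment in memory
#'
#' The study design mirrors a label-free time-lapse acquisition: each
#' experimental condition (class) is recorded in its own videos; cells are
#' detected per frame by the Circular Hough Transform, linked into tracks by
#' Munkres assignment, grouped into spatial clusters, and a raw 63x63 ROI
#' sequence is extracted per track. Track labels are the condition of the
#' video they come from.
#'
#' @param class_params list of per-class morphodynamic parameter lists (see
#'   [simulation_config()]).
#' @param n_videos_per_class videos recorded per condition.
#' @param n_clusters,cells_per_cluster cluster layout per video.
#' @param image_size,n_frames video geometry.
#' @param inter_cluster_spacing um between cluster centres.
#' @param seed master seed; every video derives its own sub-seed.
#' @param detection a [detection_config()].
#' @param preprocess_cfg a [preprocess_config()] (ROI geometry).
#' @param use_truth_tracks skip detection and build tracks directly from the
#'   generator's ground truth (used to isolate downstream stages).
#' @return list with `rois` (list of raw `roi_sequence`), `meta` (one row per
#'   track: `track_id`, `video`, `cluster_id`, `label`, `centroid_x`,
#'   `midline`), `tracks` (per-video `track_set`s) and `truth` (per-video
#'   ground truth).
#' @export
run_synthetic_experiment <- function(class_params = list(
                                       list(fluctuation_amplitude = 0),
                                       list(fluctuation_amplitude = 0.3)),
                                     n_videos_per_class = 1L,
                                     n_clusters = 4L, cells_per_cluster = 5L,
                                     image_size = c(512L, 512L),
                                     n_frames = 60L,
                                     inter_cluster_spacing = 80,
                                     seed = 1L,
                                     detection = detection_config(),
                                     preprocess_cfg = preprocess_config(),
                                     use_truth_tracks = FALSE) {
  n_classes <- length(class_params)
  rois <- list(); meta <- list(); all_tracks <- list(); truths <- list()
  vid <- 0L
  for (cls in seq_len(n_classes)) {
    for (rep_ in seq_len(n_videos_per_class)) {
      vid <- vid + 1L
      cfg <- simulation_config(image_size = image_size, n_frames = n_frames,
                               class_params = class_params,
                               n_clusters = n_clusters,
                               cells_per_cluster = cells_per_cluster,
                               inter_cluster_spacing = inter_cluster_spacing,
                               seed = seed * 1000L + vid)
      g <- generate_video(cfg, class_of_video = cls)
      if (use_truth_tracks) {
        tr <- g$truth
        tracks <- data.frame(track_id = tr$cell_id, frame = tr$frame,
                             x = tr$x_px, y = tr$y_px, radius = tr$radius_px,
                             gap = FALSE, cluster_id = NA_integer_)
        class(tracks) <- c("track_set", "data.frame")
        tracks <- identify_clusters(tracks)
      } else {
        det <- detect_video(g$video, detection)
        tracks <- link_tracks(det, n_frames = n_frames)
        if (nrow(tracks) == 0L) next
        tracks <- identify_clusters(tracks)
      }
      all_tracks[[vid]] <- tracks
      truths[[vid]] <- g$truth
      mid <- dim(g$video)[2] / 2
      for (id in unique(tracks$track_id)) {
        sub <- tracks[tracks$track_id == id, ]
        rois[[length(rois) + 1L]] <-
          extract_roi_sequence(g$video, sub, preprocess_cfg)
        meta[[length(meta) + 1L]] <- data.frame(
          track_id = paste0("v", vid, "t", id), video = paste0("v", vid),
          cluster_id = sub$cluster_id[1], label = paste0("class", cls),
          centroid_x = mean(sub$x), midline = mid)
      }
    }
  }
  list(rois = rois, meta = do.call(rbind, meta), tracks = all_tracks,
       truth = truths)
}

#' Backbone feature signals for every track of an experiment
#'
#' @param experiment result of [run_synthetic_experiment()] (or any list with
#'   `rois`).
#' @param backbone a [backbone_spec()].
#' @param config a [preprocess_config()].
#' @param mode preprocessing arm.
#' @return list of `feature_signals`, one per track.
#' @export
experiment_signals <- function(experiment, backbone = backbone_spec(),
                               config = preprocess_config(),
                               mode = "background_suppression") {
  lapply(experiment$rois, function(r) {
    backbone_features(preprocess(r, config, mode), backbone)
  })
}

#' Deep-branch track descriptors for an experiment
#'
#' @inheritParams experiment_signals
#' @return a [track_descriptors()] set.
#' @export
experiment_descriptors <- function(experiment, backbone = backbone_spec(),
                                   config = preprocess_config(),
                                   mode = "background_suppression") {
  x <- descriptor_matrix(experiment$rois, backbone, config, mode)
  track_descriptors(x, experiment$meta)
}

# ---------------------------------------------------------------------------
# file-based pipeline (CLI surface)

default_experiment_config <- function() {
  list(
    seed = 1L,
    paths = list(out = "morphodyn_out"),
    simulate = list(image_size = c(512L, 512L), n_frames = 60L,
                    n_clusters = 4L, cells_per_cluster = 5L,
                    n_videos_per_class = 1L, inter_cluster_spacing = 80,
                    class_params = list(list(fluctuation_amplitude = 0),
                                        list(fluctuation_amplitude = 0.3))),
    detect = list(radius_range_um = c(4.3, 7.6), resolution = 0.33,
                  sensitivity = 0.25),
    roi = list(roi_size = 63L, sigma_px = 18, mode = "background_suppression"),
    features = list(backbone = "fallback", dim = NULL, backbone_seed = 17L,
                    branch = "deep"),
    evaluate = list(classifier = "svm", q_low = 0.1, q_high = 0.9),
    sensitivity = list(biases = c(0, 0.3, 0.5),
                       modes = c("background_suppression", "no_preprocessing"))
  )
}

#' Read an experiment configuration
#'
#' YAML keys override the package defaults (see the vignette for the full
#' schema); unknown keys raise an error naming them.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return nested configuration list.
#' @export
read_experiment_config <- function(path = NULL) {
  cfg <- default_experiment_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  utils::modifyList(cfg, user)
}

write_provenance <- function(dir, cfg, stage) {
  resolved <- file.path(dir, paste0(stage, "_config.yaml"))
  yaml::write_yaml(cfg, resolved)
  prov <- file.path(dir, paste0(stage, "_provenance.txt"))
  writeLines(c(sprintf("stage: %s", stage),
               sprintf("seed: %d", cfg$seed),
               sprintf("config_md5: %s", unname(tools::md5sum(resolved))),
               sprintf("package: morphodyn %s",
                       as.character(utils::packageVersion("morphodyn")))),
             prov)
  invisible(prov)
}

#' Run the file-based pipeline
#'
#' Executes the requested stages in order, reading each stage's inputs from
#' `out_dir` (or producing them in the same run) and writing its artifacts
#' there, together with a resolved configuration and a provenance record
#' (seed, config hash, package version). Rerunning with an identical
#' configuration reproduces identical CSV outputs.
#'
#' Stages: `simulate` (videos + truth CSV), `track` (tracks CSV),
#' `roi` + `features` (descriptor CSV), `evaluate` (accuracy + confusion
#' CSVs at track and cluster level), `sensitivity` (bias table CSV).
#'
#' @param config configuration list from [read_experiment_config()].
#' @param stages ordered subset of
#'   `c("simulate", "track", "roi", "features", "evaluate", "sensitivity")`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list of the artifacts each stage produced.
#' @export
run_pipeline <- function(config = read_experiment_config(),
                         stages = c("simulate", "track", "roi", "features",
                                    "evaluate"),
                         out_dir = config$paths$out) {
  stages <- match.arg(stages, c("simulate", "track", "roi", "features",
                                "evaluate", "sensitivity"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  need <- function(f, stage) {
    if (!file.exists(f)) {
      stop("stage '", stage, "' requires missing artifact: ", f)
    }
    f
  }

  sim <- config$simulate
  n_classes <- length(sim$class_params)
  video_ids <- function() {
    vid <- 0L
    out <- list()
    for (cls in seq_len(n_classes)) for (r in seq_len(sim$n_videos_per_class)) {
      vid <- vid + 1L
      out[[vid]] <- list(vid = vid, class = cls)
    }
    out
  }

  if ("simulate" %in% stages) {
    for (v in video_ids()) {
      cfg <- simulation_config(image_size = sim$image_size,
                               n_frames = sim$n_frames,
                               class_params = sim$class_params,
                               n_clusters = sim$n_clusters,
                               cells_per_cluster = sim$cells_per_cluster,
                               inter_cluster_spacing = sim$inter_cluster_spacing,
                               seed = config$seed * 1000L + v$vid)
      g <- generate_video(cfg, class_of_video = v$class)
      write_video_tiff(g$video, file.path(out_dir, sprintf("video%02d.tif", v$vid)))
      write_truth_csv(g$truth, file.path(out_dir, sprintf("truth%02d.csv", v$vid)))
    }
    write_provenance(out_dir, config, "simulate")
    artifacts$simulate <- list.files(out_dir, pattern = "^(video|truth)")
  }

  if ("track" %in% stages) {
    dcfg <- detection_config(radius_range_um = config$detect$radius_range_um,
                             resolution = config$detect$resolution,
                             sensitivity = config$detect$sensitivity)
    for (v in video_ids()) {
      vf <- need(file.path(out_dir, sprintf("video%02d.tif", v$vid)), "track")
      video <- read_video_tiff(vf, resolution = config$detect$resolution)
      tracks <- identify_clusters(link_tracks(detect_video(video, dcfg),
                                              n_frames = dim(video)[3]))
      write_tracks_csv(tracks, file.path(out_dir, sprintf("tracks%02d.csv", v$vid)))
    }
    write_provenance(out_dir, config, "track")
    artifacts$track <- list.files(out_dir, pattern = "^tracks")
  }

  if (any(c("roi", "features") %in% stages)) {
    pcfg <- preprocess_config(roi_size = config$roi$roi_size,
                              sigma_px = config$roi$sigma_px)
    bspec <- backbone_spec(config$features$backbone, dim = config$features$dim,
                           seed = config$features$backbone_seed)
    rows <- list(); metas <- list()
    for (v in video_ids()) {
      vf <- need(file.path(out_dir, sprintf("video%02d.tif", v$vid)), "roi")
      tf <- need(file.path(out_dir, sprintf("tracks%02d.csv", v$vid)), "roi")
      video <- read_video_tiff(vf)
      tracks <- read_tracks_csv(tf)
      mid <- dim(video)[2] / 2
      for (id in unique(tracks$track_id)) {
        sub <- tracks[tracks$track_id == id, ]
        roi <- extract_roi_sequence(video, sub, pcfg)
        if (config$features$branch == "deep") {
          sig <- backbone_features(preprocess(roi, pcfg, config$roi$mode), bspec)
          d <- dynamics_descriptor(sig)
          full <- stats::setNames(numeric(length(sig$feature_ids)),
                                  sig$feature_ids)
          full[names(d)] <- d
        } else {
          full <- shape_texture_descriptor(preprocess(roi, pcfg, config$roi$mode))
        }
        rows[[length(rows) + 1L]] <- full
        metas[[length(metas) + 1L]] <- data.frame(
          track_id = paste0("v", v$vid, "t", id),
          video = paste0("v", v$vid), cluster_id = sub$cluster_id[1],
          label = paste0("class", v$class), centroid_x = mean(sub$x),
          midline = mid)
      }
    }
    desc <- cbind(do.call(rbind, metas), do.call(rbind, rows))
    utils::write.csv(desc, file.path(out_dir, "descriptors.csv"),
                     row.names = FALSE)
    write_provenance(out_dir, config, "features")
    artifacts$features <- "descriptors.csv"
  }

  if ("evaluate" %in% stages) {
    df <- utils::read.csv(need(file.path(out_dir, "descriptors.csv"),
                               "evaluate"))
    meta_cols <- c("track_id", "video", "cluster_id", "label", "centroid_x",
                   "midline")
    d <- track_descriptors(as.matrix(df[, setdiff(names(df), meta_cols)]),
                           df[, meta_cols])
    spec <- classifier_spec(config$evaluate$classifier, seed = config$seed)
    selection <- selection_config(config$evaluate$q_low, config$evaluate$q_high)
    rep_ <- half_experiment_out_cv(d, spec, selection)
    acc <- data.frame(level = c("single-track", "cluster"),
                      accuracy_mean = c(rep_$track$accuracy_mean,
                                        rep_$cluster$accuracy_mean),
                      accuracy_sd = c(rep_$track$accuracy_sd,
                                      rep_$cluster$accuracy_sd))
    utils::write.csv(acc, file.path(out_dir, "accuracy.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(rep_$track$confusion),
                     file.path(out_dir, "confusion_track.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(rep_$cluster$confusion),
                     file.path(out_dir, "confusion_cluster.csv"),
                     row.names = FALSE)
    write_provenance(out_dir, config, "evaluate")
    artifacts$evaluate <- c("accuracy.csv", "confusion_track.csv",
                            "confusion_cluster.csv")
  }

  if ("sensitivity" %in% stages) {
    pcfg <- preprocess_config(roi_size = config$roi$roi_size,
                              sigma_px = config$roi$sigma_px)
    bspec <- backbone_spec(config$features$backbone, dim = config$features$dim,
                           seed = config$features$backbone_seed)
    rois <- list(); metas <- list()
    for (v in video_ids()) {
      vf <- need(file.path(out_dir, sprintf("video%02d.tif", v$vid)), "sensitivity")
      tf <- need(file.path(out_dir, sprintf("tracks%02d.csv", v$vid)), "sensitivity")
      video <- read_video_tiff(vf)
      tracks <- read_tracks_csv(tf)
      mid <- dim(video)[2] / 2
      for (id in unique(tracks$track_id)) {
        sub <- tracks[tracks$track_id == id, ]
        rois[[length(rois) + 1L]] <- extract_roi_sequence(video, sub, pcfg)
        metas[[length(metas) + 1L]] <- data.frame(
          track_id = paste0("v", v$vid, "t", id),
          video = paste0("v", v$vid), cluster_id = sub$cluster_id[1],
          label = paste0("class", v$class), centroid_x = mean(sub$x),
          midline = mid)
      }
    }
    tab <- bias_sensitivity(rois, do.call(rbind, metas),
                            biases = config$sensitivity$biases,
                            modes = config$sensitivity$modes,
                            backbone = bspec,
                            spec = classifier_spec(config$evaluate$classifier,
                                                   seed = config$seed),
                            selection = selection_config(config$evaluate$q_low,
                                                         config$evaluate$q_high),
                            config = pcfg)
    utils::write.csv(tab, file.path(out_dir, "bias_table.csv"),
                     row.names = FALSE)
    write_provenance(out_dir, config, "sensitivity")
    artifacts$sensitivity <- "bias_table.csv"
  }
  invisible(artifacts)
}
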