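#' Frame subsampling specification
#'
#' Describes how a continuous multi-camera video record is reduced to an
#' analysis frame set: capture one frame per minute per camera inside a
#' fixed daily window. The motivating field trial kept a 357-minute
#' window across 2 cameras for 31 days, giving 714 frames per day and
#' 22,134 in total.
#'
#' @param n_minutes Retained frames per camera per day (minutes in the
#'   daily window at one frame per minute).
#' @param cameras Number of cameras.
#' @param frames_per_minute Capture rate after subsampling (default 1).
#' @param keep_every Keep every `keep_every`-th captured frame.
#' @return A list of class `"subsample_spec"`.
#' @export
subsample_spec <- function(n_minutes = 357L, cameras = 2L,
                           frames_per_minute = 1, keep_every = 1L) {
  stopifnot(n_minutes >= 1, cameras >= 1, keep_every >= 1)
  structure(list(n_minutes = n_minutes, cameras = cameras,
                 frames_per_minute = frames_per_minute,
                 keep_every = keep_every),
            class = "subsample_spec")
}

#' Expected frame counts under a subsampling scheme
#'
#' @param spec A [subsample_spec()].
#' @param n_days Number of recording days (>= 1).
#' @return List: `per_camera_per_day`, `per_day`, `total`.
#' @examples
#' subsample_count(subsample_spec(357, cameras = 2), n_days = 31)
#' @export
subsample_count <- function(spec, n_days) {
  stopifnot(n_days >= 1)
  per_cam <- spec$n_minutes * spec$frames_per_minute / spec$keep_every
  per_day <- per_cam * spec$cameras
  list(per_camera_per_day = per_cam, per_day = per_day,
       total = per_day * n_days)
}

#' Experiment configuration
#'
#' One object parameterizing a full simulate / train / detect / evaluate /
#' sweep / crop run. All randomness flows from the single master `seed`,
#' split deterministically per stage.
#'
#' @param scene A [scene_config()].
#' @param train A [train_config()].
#' @param scan A [scan_config()].
#' @param feature_families Families to train, subset of
#'   `c("haar", "lbp")`.
#' @param n_train_pos Positive training crops.
#' @param n_train_neg_frames Bird-free training frames.
#' @param n_test_frames Test frames rendered for evaluation.
#' @param iou_threshold Matching threshold for the headline metrics.
#' @param sweep_thresholds Descending thresholds for the IoU sweep.
#' @param matching_mode `"paper"` or `"one_to_one"`.
#' @param crop_region Region-of-interest [bbox()]; defaults to the scene
#'   config's `crop_region`.
#' @param seed Master seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(scene = scene_config(), train = train_config(),
                       scan = scan_config(),
                       feature_families = c("haar", "lbp"),
                       n_train_pos = 150L, n_train_neg_frames = 20L,
                       n_test_frames = 150L, iou_threshold = 0.5,
                       sweep_thresholds = seq(0.50, 0.30, by = -0.05),
                       matching_mode = "paper", crop_region = NULL,
                       seed = 1L) {
  feature_families <- match.arg(feature_families, c("haar", "lbp"),
                                several.ok = TRUE)
  structure(list(scene = scene, train = train, scan = scan,
                 feature_families = feature_families,
                 n_train_pos = as.integer(n_train_pos),
                 n_train_neg_frames = as.integer(n_train_neg_frames),
                 n_test_frames = as.integer(n_test_frames),
                 iou_threshold = iou_threshold,
                 sweep_thresholds = sweep_thresholds,
                 matching_mode = matching_mode,
                 crop_region = crop_region %||% scene$crop_region,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; nested `scene`,
#' `train` and `scan` maps override the corresponding constructor
#' defaults field by field.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  scene <- do.call(scene_config, y$scene %||% list())
  train <- do.call(train_config, y$train %||% list())
  scan <- do.call(scan_config, y$scan %||% list())
  rest <- y[setdiff(names(y), c("scene", "train", "scan"))]
  do.call(run_config, c(list(scene = scene, train = train, scan = scan),
                        rest))
}

#' Run the full detection experiment
#'
#' Reproduces the shape of the motivating study's workflow on synthetic
#' scenes: generate a training set and a skewed test frame set; train one
#' cascade per requested feature family; detect on full frames and on
#' frames cropped to the region of interest with the SAME cascade; compute
#' the five metrics, frame-level summaries, per-frame bird counts, and an
#' IoU-threshold sweep; and write the report files.
#'
#' Outputs under `out_dir`: `metrics_table.csv` (one row per family x
#' image size, rounded to 3 decimals alongside unrounded columns),
#' `frame_summary_table.csv`, `sweep.csv`, `counts.csv` (per frame and
#' family: number of detections), and `manifest.json` (seed, config
#' checksum).
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory for report CSVs (created if needed).
#' @return Invisibly, a list with the trained detectors, detections,
#'   confusion objects, metric/summary/sweep tables and file paths.
#' @export
run_experiment <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ts <- make_training_set(cfg$scene, cfg$n_train_pos, cfg$n_train_neg_frames,
                          seed = derive_seed(cfg$seed, 101))
  frames <- list()
  anns <- list()
  with_seed(derive_seed(cfg$seed, 102), {
    for (i in seq_len(cfg$n_test_frames)) {
      fid <- sprintf("frame_%06d", i)
      sc <- render_scene_impl(cfg$scene, fid)
      frames[[fid]] <- sc$image
      anns[[fid]] <- sc$annotation
    }
  })
  gts <- do.call(rbind, anns)
  ids <- names(frames)
  crop <- as_box(cfg$crop_region)

  results <- list()
  metric_rows <- list()
  summary_rows <- list()
  sweep_rows <- list()
  count_rows <- list()
  for (fam in cfg$feature_families) {
    tc <- cfg$train
    tc$seed <- derive_seed(cfg$seed, 103 + match(fam, c("haar", "lbp")))
    det <- cascade_detector(ts$positives, ts$negatives, feature = fam,
                            config = tc, scan = cfg$scan)
    # detect once per image size, then evaluate
    dets_full <- collect_detections(det, frames, cfg$scan)
    cropped_frames <- lapply(frames, function(img) {
      img[crop$y + seq_len(crop$h), crop$x + seq_len(crop$w), drop = FALSE]
    })
    dets_crop <- collect_detections(det, cropped_frames, cfg$scan)
    gts_crop <- crop_annotations(gts, crop)
    ce <- list(
      full = local({
        cc <- confusion_counts(dets_full, gts, cfg$iou_threshold,
                               cfg$matching_mode, frame_ids = ids)
        list(counts = cc, metrics = metrics(cc))
      }),
      cropped = local({
        cc <- confusion_counts(dets_crop, gts_crop, cfg$iou_threshold,
                               cfg$matching_mode, frame_ids = ids)
        list(counts = cc, metrics = metrics(cc))
      }))
    for (size in c("full", "cropped")) {
      cc <- ce[[size]]$counts
      mt <- ce[[size]]$metrics
      fs <- frame_summary(cc)
      metric_rows[[paste(fam, size)]] <-
        data.frame(feature = fam, image = size,
                   precision = mt$precision, recall = mt$recall,
                   f_measure = mt$f_measure, fnr = mt$fnr, far = mt$far)
      summary_rows[[paste(fam, size)]] <-
        data.frame(feature = fam, image = size,
                   n_frames = fs$n_frames,
                   n_frames_with_birds = fs$n_frames_with_birds,
                   n_nobird_frames_with_fp = fs$n_nobird_frames_with_fp,
                   pct_nobird_fp_of_total = fs$pct_nobird_fp_of_total,
                   pct_nobird_fp_of_total_rounded =
                     fs$pct_nobird_fp_of_total_rounded,
                   n_bird_frames_with_tp = fs$n_bird_frames_with_tp,
                   pct_bird_tp_of_bird_frames = fs$pct_bird_tp_of_bird_frames,
                   pct_bird_tp_of_bird_frames_rounded =
                     fs$pct_bird_tp_of_bird_frames_rounded)
      pf <- cc$per_frame
      count_rows[[paste(fam, size)]] <-
        data.frame(feature = fam, image = size, frame_id = pf$frame_id,
                   n_detections = pf$n_detections, tp = pf$tp, fp = pf$fp,
                   fn = pf$fn)
    }
    # sweep on the full-image detections
    sw <- threshold_sweep(dets_full, gts, cfg$sweep_thresholds,
                          mode = cfg$matching_mode, frame_ids = ids)
    sweep_rows[[fam]] <- cbind(data.frame(feature = fam), as.data.frame(sw))
    results[[fam]] <- list(detector = det, crop_eval = ce, sweep = sw,
                           detections_full = dets_full)
  }

  metric_grid <- do.call(rbind, metric_rows)
  summary_grid <- do.call(rbind, summary_rows)
  sweep_grid <- do.call(rbind, sweep_rows)
  counts_grid <- do.call(rbind, count_rows)
  paths <- report_tables(metric_grid, summary_grid, sweep_grid, counts_grid,
                         out_dir)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(schema = "birdcascade/run",
                            schema_version = 1L, seed = cfg$seed,
                            feature_families = cfg$feature_families,
                            n_test_frames = cfg$n_test_frames,
                            iou_threshold = cfg$iou_threshold,
                            matching_mode = cfg$matching_mode,
                            config_checksum = config_checksum(cfg)),
                       manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(results = results, frames = frames, ground_truth = gts,
                 metrics = metric_grid, frame_summaries = summary_grid,
                 sweep = sweep_grid, counts = counts_grid,
                 paths = c(paths, manifest = manifest)))
}

collect_detections <- function(det, frames, scan) {
  out <- lapply(names(frames), function(fid) {
    detect(det, frames[[fid]], scan, frame_id = fid)
  })
  do.call(rbind, out)
}

# cheap deterministic checksum of the config (no digest dependency)
config_checksum <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Write the report tables of an experiment
#'
#' Emits the metric grid (one row per feature family and image size, with
#' values both unrounded and rounded to 3 decimals), the frame-level
#' summary grid, the IoU sweep, and the per-frame counts as CSV files.
#' Missing grid cells are written as explicit `NA`.
#'
#' @param metric_grid,summary_grid,sweep_grid,counts_grid Data frames as
#'   assembled by [run_experiment()].
#' @param out_dir Output directory.
#' @return Named character vector of file paths.
#' @export
report_tables <- function(metric_grid, summary_grid, sweep_grid,
                          counts_grid, out_dir) {
  mg <- metric_grid
  for (col in c("precision", "recall", "f_measure", "fnr", "far")) {
    mg[[paste0(col, "_rounded")]] <- round_half_up(mg[[col]], 3)
  }
  p1 <- file.path(out_dir, "metrics_table.csv")
  p2 <- file.path(out_dir, "frame_summary_table.csv")
  p3 <- file.path(out_dir, "sweep.csv")
  p4 <- file.path(out_dir, "counts.csv")
  utils::write.csv(mg, p1, row.names = FALSE)
  utils::write.csv(summary_grid, p2, row.names = FALSE)
  utils::write.csv(sweep_grid, p3, row.names = FALSE)
  utils::write.csv(counts_grid, p4, row.names = FALSE)
  c(metrics = p1, frame_summaries = p2, sweep = p3, counts = p4)
}

#' Reference frame tallies from the motivating field trial
#'
#' Loads the published frame tallies and metric tables of the feeding
#' station field trial this package emulates, shipped as plain-text CSVs.
#' Useful for checking the package's reporting arithmetic against printed
#' numbers.
#'
#' @param which One of `"frame_counts"` (per-table totals, bird and
#'   no-bird frame counts), `"metrics"` (precision/recall/F/FNR/FAR per
#'   detector, table and image size), `"frame_summary"` (frames with
#'   false positives / true positives and printed percentages).
#' @return A data frame.
#' @export
fieldtrial_reference <- function(which = c("frame_counts", "metrics",
                                           "frame_summary")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("fieldtrial_", which, ".csv"),
                      package = "birdcascade", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
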