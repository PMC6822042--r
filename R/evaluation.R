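#' Match detections to ground truth in one frame
#'
#' Two matching conventions are provided:
#'
#' * `mode = "paper"` (default, the convention of the motivating field
#'   study): every detection whose best IoU against any ground truth
#'   exceeds `t` is a true positive — several detections may score on the
#'   same bird, which is why recall can exceed 1 — and every ground truth
#'   with no detection exceeding `t` is a false negative.
#' * `mode = "one_to_one"`: greedy matching by descending IoU with each
#'   ground truth consumable once, the stricter convention common in
#'   detection benchmarks.
#'
#' The IoU comparison is strict (`> t`) by default, matching the study's
#' "over 0.5" rule; set `cmp = ">="` for sensitivity analysis.
#'
#' @param dets,gts Box data frames (columns `x`, `y`, `w`, `h`) or lists
#'   of [bbox()] for a single frame.
#' @param t IoU threshold in (0, 1).
#' @param mode `"paper"` or `"one_to_one"`.
#' @param cmp `">"` (strict, default) or `">="`.
#' @return A list with integer fields `tp`, `fp`, `fn`.
#' @export
match_frame <- function(dets, gts, t = 0.5,
                        mode = c("paper", "one_to_one"), cmp = c(">", ">=")) {
  mode <- match.arg(mode); cmp <- match.arg(cmp)
  stopifnot(t > 0, t < 1)
  dets <- boxes_df(dets); gts <- boxes_df(gts)
  nd <- nrow(dets); ng <- nrow(gts)
  exceeds <- if (cmp == ">") function(x) x > t else function(x) x >= t
  if (nd == 0 && ng == 0) return(list(tp = 0L, fp = 0L, fn = 0L))
  m <- iou_matrix(dets, gts)
  if (mode == "paper") {
    det_hit <- if (ng > 0 && nd > 0) exceeds(apply(m, 1, max)) else rep(FALSE, nd)
    gt_hit <- if (ng > 0 && nd > 0) exceeds(apply(m, 2, max)) else rep(FALSE, ng)
    tp <- sum(det_hit); fp <- nd - tp; fn <- sum(!gt_hit)
  } else {
    used_d <- rep(FALSE, nd); used_g <- rep(FALSE, ng)
    tp <- 0L
    if (nd > 0 && ng > 0) {
      repeat {
        m2 <- m
        m2[used_d, ] <- -1
        m2[, used_g] <- -1
        best <- which(m2 == max(m2), arr.ind = TRUE)[1, , drop = TRUE]
        if (!exceeds(m2[best[1], best[2]])) break
        used_d[best[1]] <- TRUE; used_g[best[2]] <- TRUE
        tp <- tp + 1L
        if (all(used_d) || all(used_g)) break
      }
    }
    fp <- nd - tp; fn <- ng - tp
  }
  list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

#' Aggregate confusion counts over a frame set
#'
#' Applies [match_frame()] to every frame and tallies aggregate and
#' per-frame counts. Frames with neither detections nor ground truth still
#' count toward the frame totals, so pass `frame_ids` covering the whole
#' frame set (by default the union of ids seen in `dets` and `gts`).
#'
#' @param dets,gts Data frames with columns `frame_id`, `x`, `y`, `w`, `h`.
#' @param frame_ids Character vector of all frame ids in the evaluation
#'   set.
#' @inheritParams match_frame
#' @return An object of class `"confusion_counts"`: fields `tp`, `fp`,
#'   `fn`, `iou_threshold`, `matching_mode`, and `per_frame` (one row per
#'   frame: `frame_id`, `has_gt`, `any_detection`, `any_tp`, `any_fp`,
#'   `tp`, `fp`, `fn`, `n_detections`).
#' @export
confusion_counts <- function(dets, gts, t = 0.5,
                             mode = c("paper", "one_to_one"),
                             cmp = c(">", ">="), frame_ids = NULL) {
  mode <- match.arg(mode); cmp <- match.arg(cmp)
  if (is.null(frame_ids)) {
    frame_ids <- sort(unique(c(as.character(dets$frame_id),
                               as.character(gts$frame_id))))
  }
  frame_ids <- as.character(frame_ids)
  rows <- lapply(frame_ids, function(fid) {
    d <- dets[as.character(dets$frame_id) == fid, , drop = FALSE]
    g <- gts[as.character(gts$frame_id) == fid, , drop = FALSE]
    mm <- match_frame(d, g, t, mode, cmp)
    data.frame(frame_id = fid, has_gt = nrow(g) > 0,
               any_detection = nrow(d) > 0,
               any_tp = mm$tp > 0, any_fp = mm$fp > 0,
               tp = mm$tp, fp = mm$fp, fn = mm$fn,
               n_detections = nrow(d))
  })
  per_frame <- do.call(rbind, rows) %||%
    data.frame(frame_id = character(0), has_gt = logical(0),
               any_detection = logical(0), any_tp = logical(0),
               any_fp = logical(0), tp = integer(0), fp = integer(0),
               fn = integer(0), n_detections = integer(0))
  structure(list(tp = sum(per_frame$tp), fp = sum(per_frame$fp),
                 fn = sum(per_frame$fn), iou_threshold = t,
                 matching_mode = mode, per_frame = per_frame),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (IoU %s %.2f, mode %s): TP %d, FP %d, FN %d over %d frames\n",
              ">", x$iou_threshold, x$matching_mode, x$tp, x$fp, x$fn,
              nrow(x$per_frame)))
  invisible(x)
}

#' F-measure from precision and recall
#'
#' The harmonic mean `2 P R / (P + R)`; `NA` when both are zero or either
#' is undefined.
#'
#' @param precision,recall Numeric values (recall may exceed 1 under
#'   `"paper"` matching).
#' @return The F-measure.
#' @export
f_measure <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Detection metrics from confusion counts
#'
#' Computes precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F-measure,
#' false-negative rate `FN/(TP+FN)` and false alarm rate `FP/(TP+FP)`.
#' A ratio with a zero denominator is reported as `NA` (never as 0) with a
#' message, so undefined cells cannot silently skew downstream sweeps.
#' `far + precision = 1` and, under one-to-one matching,
#' `fnr + recall = 1`, whenever defined.
#'
#' @param counts A `"confusion_counts"` object, or a list with fields
#'   `tp`, `fp`, `fn`.
#' @return An object of class `"metrics_report"` with fields `precision`,
#'   `recall`, `f_measure`, `fnr`, `far`, `iou_threshold`,
#'   `matching_mode`.
#' @export
metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  ratio <- function(num, den, what) {
    if (den == 0) {
      message(what, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  p <- ratio(tp, tp + fp, "precision")
  r <- ratio(tp, tp + fn, "recall")
  structure(list(precision = p, recall = r, f_measure = f_measure(p, r),
                 fnr = if (is.na(r)) NA_real_ else fn / (tp + fn),
                 far = if (is.na(p)) NA_real_ else fp / (tp + fp),
                 iou_threshold = counts$iou_threshold %||% NA_real_,
                 matching_mode = counts$matching_mode %||% NA_character_),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  F %.3f  FNR %.3f  FAR %.3f\n",
              x$precision, x$recall, x$f_measure, x$fnr, x$far))
  invisible(x)
}

#' Frame-level detection summary
#'
#' The frame-occupancy view of performance: how many object-free frames
#' carry at least one false positive, and how many object-bearing frames
#' carry at least one true positive. Following the reporting convention of
#' the motivating study, the false-positive percentage is taken over ALL
#' frames, while the true-positive percentage is over object-bearing
#' frames only. Percentages are reported both unrounded and rounded
#' half-up to the nearest integer.
#'
#' @param x A `"confusion_counts"` object or its `per_frame` data frame.
#' @return An object of class `"frame_summary"`.
#' @export
frame_summary <- function(x) {
  pf <- if (inherits(x, "confusion_counts")) x$per_frame else x
  if (anyDuplicated(pf$frame_id)) stop("every frame must appear exactly once")
  n <- nrow(pf)
  n_bird <- sum(pf$has_gt)
  n_nobird <- n - n_bird
  n_nobird_fp <- sum(!pf$has_gt & pf$any_fp)
  n_bird_tp <- sum(pf$has_gt & pf$any_tp)
  pcts <- summary_percentages(n, n_bird, n_nobird_fp, n_bird_tp)
  structure(c(list(n_frames = n, n_frames_with_birds = n_bird,
                   n_frames_without_birds = n_nobird,
                   n_nobird_frames_with_fp = n_nobird_fp,
                   n_bird_frames_with_tp = n_bird_tp),
              pcts),
            class = "frame_summary")
}

#' Frame-summary percentages from raw counts
#'
#' The arithmetic behind [frame_summary()], usable directly on published
#' tallies: `pct_nobird_fp_of_total = 100 * n_nobird_fp_frames / n_frames`
#' (denominator is ALL frames) and
#' `pct_bird_tp_of_bird_frames = 100 * n_bird_tp_frames / n_bird_frames`.
#'
#' @param n_frames Total frames.
#' @param n_bird_frames Frames with at least one object.
#' @param n_nobird_fp_frames Object-free frames with >= 1 false positive.
#' @param n_bird_tp_frames Object frames with >= 1 true positive.
#' @return List with the two percentages, unrounded and rounded half-up
#'   to integers; the bird-frame percentage is `NA` when there are no
#'   object frames.
#' @export
summary_percentages <- function(n_frames, n_bird_frames,
                                n_nobird_fp_frames, n_bird_tp_frames) {
  p1 <- 100 * n_nobird_fp_frames / n_frames
  p2 <- if (n_bird_frames == 0) {
    message("bird-frame percentage undefined: no frames with birds")
    NA_real_
  } else {
    100 * n_bird_tp_frames / n_bird_frames
  }
  list(pct_nobird_fp_of_total = p1,
       pct_bird_tp_of_bird_frames = p2,
       pct_nobird_fp_of_total_rounded = round_half_up(p1),
       pct_bird_tp_of_bird_frames_rounded =
         if (is.na(p2)) NA_real_ else round_half_up(p2))
}

#' @export
print.frame_summary <- function(x, ...) {
  cat(sprintf("%d frames: %d with birds, %d without\n",
              x$n_frames, x$n_frames_with_birds, x$n_frames_without_birds))
  cat(sprintf("  no-bird frames with false positives: %d (%.0f%% of all frames)\n",
              x$n_nobird_frames_with_fp, x$pct_nobird_fp_of_total_rounded))
  cat(sprintf("  bird frames with true positives:     %d (%.0f%% of bird frames)\n",
              x$n_bird_frames_with_tp, x$pct_bird_tp_of_bird_frames_rounded))
  invisible(x)
}

#' Sweep the IoU matching threshold
#'
#' Recomputes precision and recall at a descending series of IoU
#' thresholds (by default 0.50 down to 0.30 in 0.05 steps) from a single
#' pass over the per-frame IoU values — loosening the threshold can only
#' promote detections and ground truths, so both metrics are
#' non-increasing in the threshold; the attribute `"monotone"` records
#' that this held.
#'
#' @inheritParams confusion_counts
#' @param thresholds Strictly decreasing thresholds in (0, 1).
#' @return Data frame of class `"sweep_result"`: `iou_threshold`,
#'   `precision`, `recall`, `f_measure`, `tp`, `fp`, `fn`.
#' @export
threshold_sweep <- function(dets, gts, thresholds = seq(0.50, 0.30, by = -0.05),
                            mode = c("paper", "one_to_one"), cmp = c(">", ">="),
                            frame_ids = NULL) {
  mode <- match.arg(mode); cmp <- match.arg(cmp)
  stopifnot(all(thresholds > 0), all(thresholds < 1),
            all(diff(thresholds) < 0))
  if (is.null(frame_ids)) {
    frame_ids <- sort(unique(c(as.character(dets$frame_id),
                               as.character(gts$frame_id))))
  }
  # cache the per-frame IoU matrices once
  cache <- lapply(as.character(frame_ids), function(fid) {
    d <- boxes_df(dets[as.character(dets$frame_id) == fid, , drop = FALSE])
    g <- boxes_df(gts[as.character(gts$frame_id) == fid, , drop = FALSE])
    list(m = iou_matrix(d, g), nd = nrow(d), ng = nrow(g))
  })
  exceeds <- if (cmp == ">") function(x, t) x > t else function(x, t) x >= t
  rows <- lapply(thresholds, function(t) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (fc in cache) {
      if (mode == "paper") {
        det_best <- if (fc$nd > 0 && fc$ng > 0) apply(fc$m, 1, max) else numeric(fc$nd)
        gt_best <- if (fc$nd > 0 && fc$ng > 0) apply(fc$m, 2, max) else numeric(fc$ng)
        tpf <- sum(exceeds(det_best, t))
        tp <- tp + tpf; fp <- fp + fc$nd - tpf
        fn <- fn + sum(!exceeds(gt_best, t))
      } else {
        mm <- match_frame_cached(fc, t, exceeds)
        tp <- tp + mm$tp; fp <- fp + mm$fp; fn <- fn + mm$fn
      }
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    data.frame(iou_threshold = t, precision = p, recall = r,
               f_measure = f_measure(p, r), tp = tp, fp = fp, fn = fn)
  })
  out <- do.call(rbind, rows)
  mono <- all(diff(out$precision) >= -1e-12, na.rm = TRUE) &&
    all(diff(out$recall) >= -1e-12, na.rm = TRUE)
  attr(out, "monotone") <- mono
  class(out) <- c("sweep_result", "data.frame")
  out
}

# greedy one-to-one matching on a cached IoU matrix
match_frame_cached <- function(fc, t, exceeds) {
  nd <- fc$nd; ng <- fc$ng
  tp <- 0L
  if (nd > 0 && ng > 0) {
    m2 <- fc$m
    repeat {
      best <- which(m2 == max(m2), arr.ind = TRUE)[1, , drop = TRUE]
      if (!exceeds(m2[best[1], best[2]], t)) break
      m2[best[1], ] <- -1
      m2[, best[2]] <- -1
      tp <- tp + 1L
      if (tp == min(nd, ng)) break
    }
  }
  list(tp = tp, fp = nd - tp, fn = ng - tp)
}

#' Crop ablation: same detector, full vs region-of-interest frames
#'
#' Re-runs the SAME trained cascade on frames cropped to a region of
#' interest (the protocol of the motivating study: the detector is not
#' retrained for the crop). Ground-truth boxes are kept only if strictly
#' more than half of their area lies inside the crop, then clipped and
#' translated into crop coordinates; a box straddling the boundary 50/50
#' is dropped.
#'
#' @param frames Named list of grayscale frames (names are frame ids).
#' @param annotations Ground-truth data frame (`frame_id`, `x`, `y`, `w`,
#'   `h`).
#' @param crop A [bbox()] inside the frame bounds.
#' @param detector A fitted [cascade_detector()].
#' @inheritParams match_frame
#' @param scan Optional [scan_config()] override.
#' @return List with elements `full` and `cropped`, each containing
#'   `counts` (a `"confusion_counts"`) and `metrics` (a
#'   `"metrics_report"`), plus `gts_cropped`, the translated ground truth.
#' @export
crop_eval <- function(frames, annotations, crop, detector, t = 0.5,
                      mode = c("paper", "one_to_one"), scan = NULL) {
  mode <- match.arg(mode)
  crop <- as_box(crop)
  scan <- scan %||% detector$scan
  ids <- names(frames)
  stopifnot(!is.null(ids))
  fr1 <- frames[[1]]
  if (crop$x + crop$w > ncol(fr1) || crop$y + crop$h > nrow(fr1)) {
    stop("crop region exceeds frame bounds")
  }
  dets_full <- do.call(rbind, lapply(ids, function(fid) {
    detect(detector, frames[[fid]], scan, frame_id = fid)
  }))
  dets_crop <- do.call(rbind, lapply(ids, function(fid) {
    img <- frames[[fid]]
    sub <- img[crop$y + seq_len(crop$h), crop$x + seq_len(crop$w), drop = FALSE]
    detect(detector, sub, scan, frame_id = fid)
  }))
  gts_crop <- crop_annotations(annotations, crop)
  if (nrow(gts_crop) == 0 && any(as.character(annotations$frame_id) %in% ids)) {
    message("crop excludes all ground truth; cropped recall will be undefined")
  }
  cf <- confusion_counts(dets_full, annotations, t, mode, frame_ids = ids)
  cc <- confusion_counts(dets_crop, gts_crop, t, mode, frame_ids = ids)
  list(full = list(counts = cf, metrics = metrics(cf)),
       cropped = list(counts = cc, metrics = metrics(cc)),
       gts_cropped = gts_crop)
}

#' Translate ground truth into crop coordinates
#'
#' Boxes with more than half their area inside the crop are clipped to it
#' and shifted so the crop origin becomes (0, 0); all others are dropped.
#'
#' @param annotations Ground-truth data frame.
#' @param crop A [bbox()].
#' @return The translated annotation data frame.
#' @export
crop_annotations <- function(annotations, crop) {
  crop <- as_box(crop)
  keep <- list()
  for (i in seq_len(nrow(annotations))) {
    b <- as_box(annotations[i, c("x", "y", "w", "h")])
    inside <- bbox_inside_area(b, crop)
    if (inside <= 0.5 * b$w * b$h) next
    cb <- bbox_clip(b, crop)
    row <- annotations[i, , drop = FALSE]
    row$x <- cb$x - crop$x; row$y <- cb$y - crop$y
    row$w <- cb$w; row$h <- cb$h
    keep[[length(keep) + 1]] <- row
  }
  if (length(keep) == 0) {
    out <- annotations[0, , drop = FALSE]
    return(out)
  }
  do.call(rbind, keep)
}
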