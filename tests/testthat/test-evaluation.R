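test_that("IoU matches pixel rasterization and is a symmetric [0,1] statistic", {
  b <- bbox(3, 4, 10, 6)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(bbox(0, 0, 5, 5), bbox(10, 10, 3, 3)), 0)

  set.seed(17)
  for (i in 1:200) {
    a <- rand_box(); b2 <- rand_box()
    v <- iou(a, b2)
    expect_equal(v, raster_iou(a, b2))
    expect_equal(v, iou(b2, a))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("frame matching follows the study convention and the one-to-one variant", {
  z <- match_frame(list(), list(), 0.5)
  expect_equal(c(z$tp, z$fp, z$fn), c(0L, 0L, 0L))

  # two detections both overlapping one ground truth above threshold:
  # both count as true positives under the study convention
  gt <- list(bbox(10, 10, 20, 20))
  dets <- list(bbox(11, 10, 20, 20), bbox(10, 12, 20, 20))
  mp <- match_frame(dets, gt, 0.5, mode = "paper")
  expect_equal(c(mp$tp, mp$fp, mp$fn), c(2L, 0L, 0L))
  # ... but only one under one-to-one greedy matching
  m1 <- match_frame(dets, gt, 0.5, mode = "one_to_one")
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(1L, 1L, 0L))

  # unmatched ground truth becomes a false negative; stray detection a
  # false positive
  mm <- match_frame(list(bbox(100, 100, 10, 10)), gt, 0.5)
  expect_equal(c(mm$tp, mm$fp, mm$fn), c(0L, 1L, 1L))

  # the threshold comparison is strict by default (IoU must exceed t)
  a <- bbox(0, 0, 10, 10); b <- bbox(0, 5, 10, 10)   # IoU = 1/3
  expect_equal(match_frame(list(a), list(b), 1 / 3)$tp, 0L)
  expect_equal(match_frame(list(a), list(b), 1 / 3, cmp = ">=")$tp, 1L)
})

test_that("matching respects counting bounds over random scenes", {
  set.seed(31)
  for (i in 1:50) {
    dets <- boxes_df(replicate(sample.int(6, 1), rand_box(), simplify = FALSE))
    gts <- boxes_df(replicate(sample.int(4, 1), rand_box(), simplify = FALSE))
    mp <- match_frame(dets, gts, 0.3, mode = "paper")
    m1 <- match_frame(dets, gts, 0.3, mode = "one_to_one")
    expect_lte(mp$tp, nrow(dets))
    expect_lte(m1$tp, min(nrow(dets), nrow(gts)))
    expect_equal(mp$tp + mp$fp, nrow(dets))
    expect_equal(m1$tp + m1$fn, nrow(gts))
  }
})

test_that("metric ratios reproduce printed-table arithmetic and guard zero denominators", {
  # published precision/recall pair: F-measure rounds to the printed value
  round_half_up <- getFromNamespace("round_half_up", "birdcascade")
  expect_equal(round_half_up(f_measure(0.010, 0.542), 3), 0.020)

  m <- metrics(list(tp = 3, fp = 1, fn = 2))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f_measure, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$fnr, 0.4)
  expect_equal(m$far, 0.25)

  perfect <- metrics(list(tp = 5, fp = 0, fn = 0))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f_measure), c(1, 1, 1))
  expect_equal(c(perfect$fnr, perfect$far), c(0, 0))

  expect_message(und <- metrics(list(tp = 0, fp = 0, fn = 3)), "undefined")
  expect_true(is.na(und$precision))
  expect_false(is.na(und$recall))
  expect_equal(und$recall, 0)

  # complementarity whenever defined: FAR = 1 - precision, and under
  # one-to-one matching FNR = 1 - recall
  set.seed(41)
  for (i in 1:25) {
    counts <- list(tp = sample.int(20, 1), fp = sample.int(20, 1),
                   fn = sample.int(20, 1))
    m <- metrics(counts)
    expect_equal(m$far + m$precision, 1)
    expect_equal(m$fnr + m$recall, 1)
  }
})

test_that("frame summaries use the documented denominators", {
  p <- summary_percentages(n_frames = 1825 + 500, n_bird_frames = 1825,
                          n_nobird_fp_frames = 0, n_bird_tp_frames = 1116)
  expect_equal(p$pct_bird_tp_of_bird_frames_rounded, 61)

  # the false-positive percentage is over ALL frames
  p <- summary_percentages(n_frames = 11067, n_bird_frames = 1825,
                          n_nobird_fp_frames = 8927, n_bird_tp_frames = 0)
  expect_equal(p$pct_nobird_fp_of_total_rounded, 81)
  # using only the no-bird frames as denominator would give 97, not 81
  round_half_up <- getFromNamespace("round_half_up", "birdcascade")
  expect_equal(round_half_up(100 * 8927 / 9242), 97)

  expect_message(p0 <- summary_percentages(10, 0, 2, 0), "undefined")
  expect_true(is.na(p0$pct_bird_tp_of_bird_frames))

  # assembled from per-frame matching
  dets <- data.frame(frame_id = c("a", "c"), x = c(0, 50), y = c(0, 50),
                     w = c(10, 10), h = c(10, 10))
  gts <- data.frame(frame_id = c("a", "b"), x = c(1, 0), y = c(0, 0),
                    w = c(10, 10), h = c(10, 10))
  cc <- confusion_counts(dets, gts, 0.5, frame_ids = c("a", "b", "c", "d"))
  fs <- frame_summary(cc)
  expect_equal(fs$n_frames, 4)
  expect_equal(fs$n_frames_with_birds, 2)
  expect_equal(fs$n_nobird_frames_with_fp, 1)  # frame c
  expect_equal(fs$n_bird_frames_with_tp, 1)    # frame a
  expect_equal(fs$pct_nobird_fp_of_total, 25)
  expect_equal(fs$pct_bird_tp_of_bird_frames, 50)
  expect_error(frame_summary(rbind(cc$per_frame, cc$per_frame)), "exactly once")

  # no detections anywhere: both counts zero
  cc0 <- confusion_counts(dets[0, ], gts, 0.5, frame_ids = c("a", "b"))
  fs0 <- frame_summary(cc0)
  expect_equal(fs0$n_nobird_frames_with_fp, 0)
  expect_equal(fs0$n_bird_frames_with_tp, 0)
})

test_that("threshold sweeps are monotone and agree with scratch recomputation", {
  # perfect detections: unity at every threshold
  gts <- data.frame(frame_id = "a", x = 5, y = 5, w = 12, h = 12)
  sw <- threshold_sweep(gts, gts)
  expect_equal(sw$precision, rep(1, 5))
  expect_equal(sw$recall, rep(1, 5))
  expect_equal(sw$iou_threshold, seq(0.50, 0.30, by = -0.05))

  # a detection at IoU 0.46 flips from FP at t = 0.50 to TP at t = 0.45
  det46 <- data.frame(frame_id = "a", x = 3, y = 1, w = 10, h = 10)
  gt46 <- data.frame(frame_id = "a", x = 0, y = 0, w = 10, h = 10)
  expect_equal(round(iou(det46, gt46), 2), 0.46)
  sw <- threshold_sweep(det46, gt46, thresholds = c(0.50, 0.45))
  expect_equal(sw$tp, c(0L, 1L))
  expect_equal(sw$fp, c(1L, 0L))

  # random scenes: the cached sweep equals match_frame recomputed from
  # scratch at every threshold, in both matching modes
  set.seed(53)
  dets <- data.frame(frame_id = sample(letters[1:4], 25, replace = TRUE),
                     boxes_df(replicate(25, rand_box(), simplify = FALSE)))
  gts <- data.frame(frame_id = sample(letters[1:5], 12, replace = TRUE),
                    boxes_df(replicate(12, rand_box(), simplify = FALSE)))
  for (mode in c("paper", "one_to_one")) {
    sw <- threshold_sweep(dets, gts, mode = mode)
    expect_true(attr(sw, "monotone"))
    for (r in seq_len(nrow(sw))) {
      t <- sw$iou_threshold[r]
      agg <- c(tp = 0L, fp = 0L, fn = 0L)
      for (fid in letters[1:5]) {
        mm <- match_frame(dets[dets$frame_id == fid, ],
                          gts[gts$frame_id == fid, ], t, mode)
        agg <- agg + c(mm$tp, mm$fp, mm$fn)
      }
      expect_equal(c(sw$tp[r], sw$fp[r], sw$fn[r]), unname(agg))
    }
    expect_true(all(diff(sw$precision) >= 0 | is.na(diff(sw$precision))))
    expect_true(all(diff(sw$recall) >= 0 | is.na(diff(sw$recall))))
  }
})

test_that("crop translation applies the majority-inside rule", {
  crop <- bbox(10, 10, 40, 40)
  ann <- data.frame(frame_id = "a",
                    x = c(15, 0, 5, 48),
                    y = c(15, 0, 12, 12),
                    w = c(10, 8, 10, 10),
                    h = c(10, 8, 10, 10),
                    label = "bird")
  out <- crop_annotations(ann, crop)
  # only box 1 survives: box 2 is fully outside, box 3 straddles exactly
  # 50/50 in x, box 4 has just 2 of 10 columns inside
  expect_equal(nrow(out), 1)
  expect_equal(out$x[1], 5); expect_equal(out$y[1], 5)
  expect_equal(out$w[1], 10); expect_equal(out$h[1], 10)

  # strict majority: a box exactly half inside is dropped
  half <- data.frame(frame_id = "a", x = 5, y = 20, w = 10, h = 10)
  expect_equal(nrow(crop_annotations(half, crop)), 0)
})

test_that("cropping to the full frame reproduces the full-image evaluation", {
  det <- fixture_cascade("haar")
  batch <- render_batch(fixture_scene_cfg(), 6, seed = 1234)
  full_crop <- bbox(0, 0, ncol(batch$frames[[1]]), nrow(batch$frames[[1]]))
  ce <- crop_eval(batch$frames, batch$gts, full_crop, det)
  expect_equal(ce$cropped$counts$tp, ce$full$counts$tp)
  expect_equal(ce$cropped$counts$fp, ce$full$counts$fp)
  expect_equal(ce$cropped$counts$fn, ce$full$counts$fn)
  expect_equal(ce$cropped$metrics$precision, ce$full$metrics$precision)
})
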