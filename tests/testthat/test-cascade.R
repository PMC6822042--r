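test_that("weak training matches exhaustive stump search and boosting symmetry", {
  # perfectly separable 1-D feature: zero weighted error before clamping
  v <- matrix(c(1, 2, 10, 11), 4, 1)
  y <- c(-1, -1, 1, 1)
  w <- rep(0.25, 4)
  wk <- train_weak(v, y, w, "haar")
  expect_equal(wk$err, 0)
  expect_equal(ifelse(wk$polarity * v[, 1] < wk$polarity * wk$threshold, 1, -1),
               y)

  # weighted 4-sample set against brute-force search over all
  # thresholds and polarities
  v <- matrix(c(3, 1, 4, 2), 4, 1)
  y <- c(1, -1, 1, -1)
  w <- c(0.4, 0.3, 0.2, 0.1)
  wk <- train_weak(v, y, w, "haar")
  ref <- brute_stump(v[, 1], y, w)
  expect_equal(wk$err, ref$err)

  # flipping all labels flips the chosen polarity at the same error
  wk_f <- train_weak(v, -y, w, "haar")
  expect_equal(wk_f$err, wk$err)
  expect_equal(wk_f$polarity, -wk$polarity)

  expect_error(train_weak(v, rep(1, 4), w, "haar"), "single class")

  # LUT learner: votes follow the weighted majority per code
  codes <- matrix(c(0L, 0L, 7L, 7L, 3L), 5, 1)
  y <- c(1, 1, -1, -1, 1)
  wk <- train_weak(codes, y, rep(0.2, 5), "lbp")
  expect_equal(wk$lut[1], 1L)    # code 0 -> positive
  expect_equal(wk$lut[8], -1L)   # code 7 -> negative
  expect_equal(wk$lut[200], -1L) # unseen code -> negative
  expect_equal(wk$err, 0)
})

test_that("stage training reaches its targets and sets the sort-based threshold", {
  set.seed(21)
  # linearly separable toy windows: one weak classifier, zero FPR
  pos <- matrix(rnorm(30, mean = 10), 30, 1)
  neg <- matrix(rnorm(50, mean = -10), 50, 1)
  cfg <- train_config(stage_fpr_target = 0.2, stage_tpr_target = 0.995,
                      max_weak_per_stage = 10)
  st <- train_stage(pos, neg, "haar", cfg)
  expect_length(st$weaks, 1)
  expect_equal(st$achieved_fpr, 0)
  expect_false(st$failed)

  # the stage threshold equals the k-th largest positive score found by
  # direct sort-and-scan, k = ceiling(tpr_target * n_pos)
  pos <- matrix(c(rnorm(40, 5, 3), rnorm(40, -1, 3)), 80, 2)
  neg <- matrix(c(rnorm(60, -5, 3), rnorm(60, 1, 3)), 120, 2)
  st <- train_stage(pos, neg, "haar", cfg)
  score_of <- function(m) {
    sc <- numeric(nrow(m))
    for (wk in st$weaks) {
      sc <- sc + wk$alpha *
        ifelse(wk$polarity * m[, wk$feature] < wk$polarity * wk$threshold,
               1, -1)
    }
    sc
  }
  pos_scores <- score_of(pos)
  k <- ceiling(0.995 * nrow(pos))
  expect_equal(st$threshold, sort(pos_scores, decreasing = TRUE)[k])
  expect_equal(st$achieved_tpr, mean(pos_scores >= st$threshold))
  expect_gte(st$achieved_tpr, 0.995)
  expect_equal(st$achieved_fpr, mean(score_of(neg) >= st$threshold))

  expect_error(train_stage(pos, pos[0, , drop = FALSE], "haar", cfg),
               "no negative samples")
})

test_that("cascade training compounds stage false-positive rates and is reproducible", {
  ts <- fixture_training_set()
  # trivially separable: dark structured sprites on flat bright
  # backgrounds (contrast features carry no signal on constant patches,
  # so the positives must contain actual structure)
  flat <- lapply(1:4, function(i) matrix(200, 60, 60))
  dark <- lapply(seq(0, 348, by = 12), function(ori) {
    sp <- make_bird_sprite(8, ori, 30)
    patch <- matrix(200, 24, 24)
    oy <- (24 - sp$h) %/% 2; ox <- (24 - sp$w) %/% 2
    sub <- patch[oy + seq_len(sp$h), ox + seq_len(sp$w)]
    sub[sp$mask] <- 30
    patch[oy + seq_len(sp$h), ox + seq_len(sp$w)] <- sub
    patch
  })
  det1 <- cascade_detector(dark, flat, feature = "haar",
                           config = train_config(max_stages = 1, seed = 2,
                                                 n_negatives = 200,
                                                 feature_cap = 60),
                           scan = scan_config(max_window = 40))
  expect_length(det1$stages, 1)
  expect_equal(det1$log$achieved_fpr, 0)

  # fpr 0.5 over 2 stages: compounded training FPR is at most 0.25
  det2 <- cascade_detector(ts$positives[1:80], ts$negatives[1:6],
                           feature = "haar",
                           config = train_config(max_stages = 2,
                                                 stage_fpr_target = 0.5,
                                                 n_negatives = 300,
                                                 feature_cap = 100, seed = 5),
                           scan = scan_config(max_window = 48))
  expect_true(all(det2$log$achieved_fpr <= 0.5))
  expect_lte(prod(det2$log$achieved_fpr), 0.25)

  # same data, config and seed: byte-identical serialized cascade
  mk <- function() cascade_detector(ts$positives[1:60], ts$negatives[1:5],
                                    feature = "lbp",
                                    config = train_config(max_stages = 2,
                                                          n_negatives = 200,
                                                          feature_cap = 80,
                                                          seed = 9),
                                    scan = scan_config(max_window = 48))
  expect_identical(write_cascade(mk()), write_cascade(mk()))

  expect_error(cascade_detector(list(), ts$negatives, "haar"), "positive")
})

test_that("cascade serialization round-trips through JSON", {
  ts <- fixture_training_set()
  det <- cascade_detector(ts$positives[1:60], ts$negatives[1:5],
                          feature = "haar",
                          config = train_config(max_stages = 2,
                                                n_negatives = 200,
                                                feature_cap = 80, seed = 9),
                          scan = scan_config(max_window = 48))
  path <- withr::local_tempfile(fileext = ".json")
  write_cascade(det, path)
  det2 <- read_cascade(path)
  expect_equal(det2$feature_family, det$feature_family)
  expect_equal(det2$base_window, det$base_window)
  expect_equal(length(det2$stages), length(det$stages))
  img <- render_scene(easy_scene_cfg(), seed = 77)$image
  expect_identical(detect(det2, img), detect(det, img))
})

test_that("window classification short-circuits and stages only shrink acceptance", {
  # one permissive stage (threshold -Inf) accepts any window
  permissive <- list(stages = list(list(
    weaks = list(list(type = "stump", feature = 1L, threshold = 0,
                      polarity = 1, alpha = 1)),
    threshold = -Inf, achieved_fpr = 1, achieved_tpr = 1, failed = FALSE)),
    pool = list(haar_feature("h2", 0, 0, 4, 4)),
    feature_family = "haar", base_window = 4L,
    config = train_config(), scan = scan_config(), log = NULL)
  class(permissive) <- "cascade_detector"
  img <- matrix(runif(64, 0, 255), 8, 8)
  ii <- integral_image(img)
  expect_true(classify_window(permissive, ii, c(0, 0)))
  expect_true(classify_window(permissive, ii, c(3, 2)))

  # hand-built 2-stage cascade on a 4x4 toy image: stage 1 accepts iff the
  # left half is darker (positive h2 value below 10), stage 2 rejects all
  toy <- rbind(c(0, 0, 255, 255),
               c(0, 0, 255, 255),
               c(0, 0, 255, 255),
               c(0, 0, 255, 255))
  ii <- integral_image(toy)
  stage1 <- list(weaks = list(list(type = "stump", feature = 1L,
                                   threshold = -10, polarity = 1, alpha = 1)),
                 threshold = 0.5, achieved_fpr = 0, achieved_tpr = 1,
                 failed = FALSE)
  stage2 <- list(weaks = stage1$weaks, threshold = 2, achieved_fpr = 0,
                 achieved_tpr = 1, failed = FALSE)
  two <- permissive
  two$pool <- list(haar_feature("h2", 0, 0, 4, 4))
  two$stages <- list(stage1)
  # h2 value = (left - right)/16 = (0 - 4*255)/16 < -10 -> h = +1, passes
  expect_true(classify_window(two, ii, c(0, 0)))
  two$stages <- list(stage1, stage2)
  expect_false(classify_window(two, ii, c(0, 0)))  # alpha*h = 1 < 2

  # monotonicity on a real cascade: accepted windows after k+1 stages are
  # a subset of those after k stages
  det <- fixture_cascade("haar")
  img <- render_scene(fixture_scene_cfg(), seed = 303)$image
  detect_raw <- getFromNamespace("detect_raw", "birdcascade")
  prev <- NULL
  for (k in seq_along(det$stages)) {
    raw <- detect_raw(det, img, det$scan, stages = k)
    keys <- paste(raw$x, raw$y, raw$w)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("detection grouping merges neighbors and drops isolated windows", {
  expect_equal(nrow(group_detections(list(), 2)), 0)

  same <- lapply(1:3, function(i) bbox(10, 12, 20, 20))
  g <- group_detections(same, min_neighbors = 3)
  expect_equal(nrow(g), 1)
  expect_equal(unlist(g[1, c("x", "y", "w", "h")], use.names = FALSE),
               c(10, 12, 20, 20))
  expect_equal(g$score, 3)

  # 5 jittered boxes + 1 far outlier: one surviving mean box
  jit <- list(bbox(10, 10, 20, 20), bbox(11, 10, 20, 20),
              bbox(10, 11, 20, 20), bbox(12, 11, 21, 21),
              bbox(11, 12, 20, 20))
  out <- c(jit, list(bbox(200, 200, 20, 20)))
  g <- group_detections(out, min_neighbors = 2)
  expect_equal(nrow(g), 1)
  expect_equal(g$x, round(mean(c(10, 11, 10, 12, 11))))
  expect_equal(g$y, round(mean(c(10, 10, 11, 11, 12))))
  expect_equal(g$w, round(mean(c(20, 20, 20, 21, 20))))
  expect_equal(g$score, 5)
})

test_that("the detector recovers planted sprites and stays quiet on blank scenes", {
  det <- fixture_cascade("haar")

  # negative control: featureless backgrounds yield (near-)empty results
  blank <- matrix(150, 192, 256)
  grad <- matrix(rep(seq(120, 170, length.out = 192), 256), 192, 256)
  set.seed(88)
  noisy <- grad + matrix(runif(192 * 256, -5, 5), 192, 256)
  n_fp <- nrow(detect(det, blank)) + nrow(detect(det, grad)) +
    nrow(detect(det, noisy))
  expect_lte(n_fp, 1)

  # a sprite pasted at a scanned scale onto clean table scenes is
  # recovered with IoU > 0.5 against the paste box
  cfg <- easy_scene_cfg()
  cfg$bird_prob <- 0
  cfg$n_containers <- 0L
  paste_sprite <- function(img, sp, x0, y0, inten = 35) {
    rr <- y0 + seq_len(sp$h); cc <- x0 + seq_len(sp$w)
    sub <- img[rr, cc]; sub[sp$mask] <- inten
    img[rr, cc] <- sub
    img
  }
  sp1 <- make_bird_sprite(15, 40, 35)
  sp2 <- make_bird_sprite(14, 130, 30)
  for (s in 1:5) {
    base <- render_scene(cfg, seed = 300 + s)$image
    img1 <- paste_sprite(base, sp1, 100, 118)
    gt1 <- data.frame(x = 100, y = 118, w = sp1$w, h = sp1$h)
    d1 <- detect(det, img1)
    expect_gte(nrow(d1), 1)
    expect_gt(max(iou_matrix(d1, gt1)), 0.5)

    # two disjoint sprites: both recovered as separate grouped detections
    img2 <- paste_sprite(img1, sp2, 175, 112)
    gt2 <- rbind(gt1, data.frame(x = 175, y = 112, w = sp2$w, h = sp2$h))
    d2 <- detect(det, img2)
    expect_gte(nrow(d2), 2)
    expect_true(all(apply(iou_matrix(d2, gt2), 2, max) > 0.5))
  }

  # frames smaller than the base window produce an empty result
  expect_message(d0 <- detect(det, matrix(100, 10, 10)), "smaller")
  expect_equal(nrow(d0), 0)
})

test_that("nuisance toggles never make recovery easier", {
  det <- fixture_cascade("haar")
  easy <- easy_scene_cfg()
  hard <- fixture_scene_cfg()
  hard$bird_prob <- 1; hard$max_birds <- 1L
  recall_of <- function(cfg, seeds) {
    hits <- 0
    for (s in seeds) {
      sc <- render_scene(cfg, seed = s)
      d <- detect(det, sc$image)
      m <- iou_matrix(d, sc$annotation)
      if (length(m) && max(m) > 0.5) hits <- hits + 1
    }
    hits / length(seeds)
  }
  seeds <- 9000 + 1:40
  expect_gte(recall_of(easy, seeds), recall_of(hard, seeds))
})
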