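#' Training configuration for a boosted cascade
#'
#' Defaults follow the study protocol this package emulates: up to 20
#' stages, each trained until its false-positive rate on the current
#' negatives is at most 0.2. The per-stage true-positive target (0.995)
#' and the remaining knobs are conventional cascade-detector defaults,
#' surfaced here so ablations can vary them.
#'
#' @param max_stages Maximum number of cascade stages (default 20).
#' @param stage_fpr_target Allowable per-stage false-positive rate on the
#'   stage's training negatives (default 0.2).
#' @param stage_tpr_target Minimum per-stage true-positive rate; the stage
#'   threshold is lowered just enough to reach it (default 0.995).
#' @param max_weak_per_stage Cap on boosting rounds per stage; hitting it
#'   without reaching `stage_fpr_target` signals stage failure and stops
#'   cascade growth.
#' @param n_negatives Number of negative windows maintained per stage
#'   (initially random crops, later mined false positives).
#' @param mining_budget Maximum windows harvested while mining hard
#'   negatives for one stage.
#' @param feature_cap Cap on the candidate feature pool size.
#' @param seed Master seed; every random draw in training derives from it,
#'   so identical config + data gives a byte-identical cascade.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(max_stages = 20L, stage_fpr_target = 0.2,
                         stage_tpr_target = 0.995, max_weak_per_stage = 40L,
                         n_negatives = 1000L, mining_budget = 20000L,
                         feature_cap = 300L, seed = 1L) {
  stopifnot(stage_fpr_target > 0, stage_fpr_target < 1,
            stage_tpr_target > 0, stage_tpr_target <= 1,
            max_stages >= 1, max_weak_per_stage >= 1, n_negatives >= 1)
  structure(list(max_stages = as.integer(max_stages),
                 stage_fpr_target = stage_fpr_target,
                 stage_tpr_target = stage_tpr_target,
                 max_weak_per_stage = as.integer(max_weak_per_stage),
                 n_negatives = as.integer(n_negatives),
                 mining_budget = as.integer(mining_budget),
                 feature_cap = as.integer(feature_cap),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Sliding-window scan configuration
#'
#' @param scale_factor Multiplicative scale step between window sizes
#'   (default 1.1).
#' @param step Slide step in pixels at base scale, scaled proportionally
#'   at larger windows (default 2).
#' @param min_neighbors Minimum number of raw windows a grouped detection
#'   must aggregate; isolated windows are discarded (default 2).
#' @param max_window Largest window side scanned (default `Inf`, i.e.
#'   limited only by the image).
#' @return A list of class `"scan_config"`.
#' @export
scan_config <- function(scale_factor = 1.1, step = 2L, min_neighbors = 2L,
                        max_window = Inf) {
  stopifnot(scale_factor > 1, step >= 1, min_neighbors >= 1)
  structure(list(scale_factor = scale_factor, step = as.integer(step),
                 min_neighbors = as.integer(min_neighbors),
                 max_window = max_window),
            class = "scan_config")
}

# epsilon clamp for the boosting weight; numeric safety only
.eps_clamp <- 1e-10

weak_alpha <- function(err) {
  err <- min(max(err, .eps_clamp), 1 - .eps_clamp)
  0.5 * log((1 - err) / err)
}

# best decision stump (threshold + polarity) for one feature's values.
# polarity p and threshold t predict +1 when p * v < p * t.
stump_search <- function(v, y, w, ord = order(v)) {
  vs <- v[ord]; ys <- y[ord]; ws <- w[ord]
  n <- length(vs)
  cum_pos <- cumsum(ws * (ys == 1))
  cum_neg <- cumsum(ws * (ys == -1))
  W_pos <- cum_pos[n]; W_neg <- cum_neg[n]
  # threshold candidates: below all values, between distinct neighbors
  cut_ok <- c(TRUE, vs[-1] > vs[-n])           # cut before position i valid
  # err with i samples on the left (v < t)
  left_pos <- c(0, cum_pos); left_neg <- c(0, cum_neg)
  err_p1 <- left_neg + (W_pos - left_pos)      # +1 left of t
  err_m1 <- left_pos + (W_neg - left_neg)      # +1 right of t
  valid <- c(cut_ok, TRUE)
  err_p1[!valid] <- Inf; err_m1[!valid] <- Inf
  i1 <- which.min(err_p1); i2 <- which.min(err_m1)
  thr_at <- function(i) {
    if (i == 1) vs[1] - 1 else if (i == n + 1) vs[n] + 1
    else (vs[i - 1] + vs[i]) / 2
  }
  if (err_p1[i1] <= err_m1[i2]) {
    list(threshold = thr_at(i1), polarity = 1, err = err_p1[i1])
  } else {
    list(threshold = thr_at(i2), polarity = -1, err = err_m1[i2])
  }
}

# best 256-entry vote table for one LBP feature's codes; unseen or tied
# bins vote -1 (background)
lut_search <- function(codes, y, w) {
  idx <- codes + 1L
  wp <- numeric(256); wn <- numeric(256)
  s <- rowsum(cbind(ifelse(y == 1, w, 0), ifelse(y == -1, w, 0)), idx)
  rows <- as.integer(rownames(s))
  wp[rows] <- s[, 1]; wn[rows] <- s[, 2]
  lut <- ifelse(wp > wn, 1L, -1L)
  list(lut = lut, err = sum(pmin(wp, wn)))
}

weak_predict <- function(weak, column) {
  if (weak$type == "stump") {
    ifelse(weak$polarity * column < weak$polarity * weak$threshold, 1, -1)
  } else {
    weak$lut[column + 1L]
  }
}

#' Train one weak classifier over a feature pool
#'
#' Selects the feature and rule (decision stump for Haar values, 256-entry
#' vote lookup for LBP codes) minimizing the weighted 0-1 error, and
#' attaches the discrete-AdaBoost weight `alpha = 0.5 * log((1 - e) / e)`
#' with `e` clamped away from 0 and 1.
#'
#' @param values Numeric (Haar) or integer-code (LBP) matrix, samples in
#'   rows and pool features in columns.
#' @param y Labels, `+1` (object) / `-1` (background); both must occur.
#' @param w Non-negative sample weights summing to 1.
#' @param family `"haar"` or `"lbp"`.
#' @param orders Optional list of precomputed sort orders per column
#'   (Haar only; a per-stage cache).
#' @return A weak-classifier list: `feature` (column index), `type`,
#'   rule fields, `alpha`, `err`.
#' @export
train_weak <- function(values, y, w, family = c("haar", "lbp"),
                       orders = NULL) {
  family <- match.arg(family)
  if (length(unique(y)) < 2) stop("degenerate training set: single class")
  if (any(w < 0)) stop("negative sample weights")
  w <- w / sum(w)
  best <- NULL
  for (j in seq_len(ncol(values))) {
    cand <- if (family == "haar") {
      stump_search(values[, j], y, w,
                   ord = if (is.null(orders)) order(values[, j]) else orders[[j]])
    } else {
      lut_search(values[, j], y, w)
    }
    if (is.null(best) || cand$err < best$err) {
      best <- cand
      best$feature <- j
    }
  }
  best$type <- if (family == "haar") "stump" else "lut"
  best$alpha <- weak_alpha(best$err)
  best
}

# stage decision: sum(alpha * h) >= threshold
stage_scores <- function(stage, values) {
  sc <- numeric(nrow(values))
  for (wk in stage$weaks) {
    sc <- sc + wk$alpha * weak_predict(wk, values[, wk$feature])
  }
  sc
}

#' Train a single cascade stage by discrete AdaBoost
#'
#' Weak classifiers are added one at a time; after each, the stage
#' threshold is set to the largest value that keeps the true-positive rate
#' at or above `config$stage_tpr_target`, and training stops as soon as
#' the false-positive rate on the supplied negatives is at most
#' `config$stage_fpr_target`. If the cap `max_weak_per_stage` is hit
#' first, the returned stage carries `failed = TRUE` and the caller stops
#' cascade growth.
#'
#' @param pos_values,neg_values Feature matrices (samples x pool) for the
#'   positive and negative windows of this stage.
#' @param family `"haar"` or `"lbp"`.
#' @param config A [train_config()].
#' @return A stage list: `weaks`, `threshold`, `achieved_fpr`,
#'   `achieved_tpr`, `failed`.
#' @export
train_stage <- function(pos_values, neg_values, family, config) {
  npos <- nrow(pos_values); nneg <- nrow(neg_values)
  if (npos == 0) stop("no positive samples")
  if (nneg == 0) stop("no negative samples")
  values <- rbind(pos_values, neg_values)
  y <- c(rep(1, npos), rep(-1, nneg))
  # balanced initial weights, the canonical cascade choice
  w <- c(rep(1 / (2 * npos), npos), rep(1 / (2 * nneg), nneg))
  orders <- if (family == "haar") {
    lapply(seq_len(ncol(values)), function(j) order(values[, j]))
  } else NULL
  weaks <- list()
  scores <- numeric(npos + nneg)
  failed <- FALSE
  repeat {
    w <- w / sum(w)
    wk <- train_weak(values, y, w, family, orders)
    h <- weak_predict(wk, values[, wk$feature])
    w <- w * exp(-wk$alpha * y * h)
    scores <- scores + wk$alpha * h
    weaks[[length(weaks) + 1]] <- wk
    pos_sc <- scores[seq_len(npos)]
    k <- ceiling(config$stage_tpr_target * npos)
    thr <- sort(pos_sc, decreasing = TRUE)[k]
    fpr <- mean(scores[npos + seq_len(nneg)] >= thr)
    tpr <- mean(pos_sc >= thr)
    if (fpr <= config$stage_fpr_target) break
    if (length(weaks) >= config$max_weak_per_stage) {
      failed <- TRUE
      break
    }
  }
  list(weaks = weaks, threshold = thr, achieved_fpr = fpr,
       achieved_tpr = tpr, failed = failed)
}

# letterbox positives / resize mined crops and stack integral images into
# an n x (base+1) x (base+1) array
window_array <- function(windows, base) {
  n <- length(windows)
  arr <- array(0, dim = c(n, base + 1, base + 1))
  for (i in seq_len(n)) {
    arr[i, , ] <- integral_image(letterbox(windows[[i]], base))
  }
  arr
}

feature_matrix <- function(arr, pool) {
  vapply(pool, function(f) eval_feature_samples(arr, f),
         numeric(dim(arr)[1]))
}

#' Fit a boosted cascade bird detector
#'
#' The fitting function of the package. Positive example windows (crops
#' around the object, any size; they are letterboxed — padded, never
#' distorted — to the square base window) and object-free background
#' frames are turned into a cascade of boosted stages over one feature
#' family. Stage `k + 1` is trained against the false positives of the
#' cascade so far, mined from the background frames (bootstrapping), so
#' the overall training false-alarm rate after `k` stages is at most
#' `stage_fpr_target^k` on the mined sets.
#'
#' @param positives List of grayscale matrices: tight crops of the object.
#' @param negatives List of grayscale frames guaranteed object-free.
#' @param feature Feature family: `"haar"` or `"lbp"` (multi-block LBP).
#' @param config A [train_config()].
#' @param scan A [scan_config()]; stored on the object and used both for
#'   hard-negative mining and as the default for [predict.cascade_detector()].
#' @param base_window Square window side in pixels (default 24).
#' @return An object of class `"cascade_detector"` with components
#'   `stages`, `pool`, `feature_family`, `base_window`, `config`, `scan`,
#'   `log` (per-stage achieved rates and negative counts) and `call`.
#'   Methods: [print.cascade_detector()], [summary.cascade_detector()],
#'   [predict.cascade_detector()], [plot.cascade_detector()].
#' @examples
#' \donttest{
#' cfg <- scene_config()
#' ts <- make_training_set(cfg, n_pos = 60, n_neg_frames = 6, seed = 7)
#' det <- cascade_detector(ts$positives, ts$negatives, feature = "lbp",
#'                         config = train_config(max_stages = 2, seed = 7))
#' det
#' }
#' @export
cascade_detector <- function(positives, negatives,
                             feature = c("lbp", "haar"),
                             config = train_config(),
                             scan = scan_config(),
                             base_window = 24L) {
  feature <- match.arg(feature)
  cl <- match.call()
  if (length(positives) == 0) stop("no positive training windows")
  if (length(negatives) == 0) stop("no negative training images")
  base <- as.integer(base_window)

  pool <- if (feature == "haar") {
    haar_feature_pool(base, max_features = config$feature_cap,
                      seed = derive_seed(config$seed, 1))
  } else {
    lbp_feature_pool(base, max_features = config$feature_cap,
                     seed = derive_seed(config$seed, 1))
  }

  pos_arr <- window_array(positives, base)
  pos_vals <- feature_matrix(pos_arr, pool)

  neg_windows <- with_seed(derive_seed(config$seed, 2),
                           sample_negative_windows(negatives, config$n_negatives, base))
  if (length(neg_windows) == 0) stop("could not sample negative windows")
  neg_vals <- feature_matrix(window_array(neg_windows, base), pool)

  stages <- list()
  log <- data.frame(stage = integer(0), n_weak = integer(0),
                    achieved_fpr = numeric(0), achieved_tpr = numeric(0),
                    n_negatives = integer(0))
  object <- NULL
  for (k in seq_len(config$max_stages)) {
    st <- train_stage(pos_vals, neg_vals, feature, config)
    if (st$failed) {
      if (length(stages) == 0) {
        stop("stage targets unreachable within max_weak_per_stage; ",
             "no cascade could be built")
      }
      message("stage ", k, " could not reach its false-positive target; ",
              "stopping cascade growth at ", length(stages), " stage(s)")
      break
    }
    stages[[k]] <- st
    log <- rbind(log, data.frame(stage = k, n_weak = length(st$weaks),
                                 achieved_fpr = st$achieved_fpr,
                                 achieved_tpr = st$achieved_tpr,
                                 n_negatives = nrow(neg_vals)))
    object <- structure(list(stages = stages, pool = pool,
                             feature_family = feature, base_window = base,
                             config = config, scan = scan, log = log,
                             call = cl),
                        class = "cascade_detector")
    if (k == config$max_stages) break
    # keep the false positives of the new stage, then mine fresh ones
    keep <- stage_scores(st, neg_vals) >= st$threshold
    neg_vals <- neg_vals[keep, , drop = FALSE]
    need <- config$n_negatives - nrow(neg_vals)
    if (need > 0) {
      mined <- with_seed(derive_seed(config$seed, 10 + k),
                         mine_hard_negatives(object, negatives, need,
                                             config$mining_budget))
      if (length(mined) > 0) {
        neg_vals <- rbind(neg_vals,
                          feature_matrix(window_array(mined, base), pool))
      }
    }
    if (nrow(neg_vals) == 0) {
      message("negative mining exhausted after stage ", k,
              "; stopping cascade growth")
      break
    }
  }
  object
}

# random square windows (side between base and the frame's short side)
# cropped from object-free frames and resized to the base window
sample_negative_windows <- function(frames, n, base) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    img <- frames[[sample.int(length(frames), 1)]]
    h <- nrow(img); w <- ncol(img)
    smax <- min(h, w)
    if (smax < base) next
    side <- sample(seq(base, smax), 1)
    ox <- sample(seq(0, w - side), 1)
    oy <- sample(seq(0, h - side), 1)
    crop <- img[oy + seq_len(side), ox + seq_len(side), drop = FALSE]
    out[[i]] <- resize_bilinear(crop, base, base)
  }
  out[!vapply(out, is.null, logical(1))]
}

# windows the current cascade still accepts on object-free frames
mine_hard_negatives <- function(object, frames, need, budget) {
  mined <- list()
  scanned <- 0
  for (idx in sample.int(length(frames))) {
    img <- frames[[idx]]
    raw <- detect_raw(object, img, object$scan)
    scanned <- scanned + attr(raw, "n_windows")
    if (nrow(raw) > 0) {
      take <- raw[sample.int(nrow(raw)), , drop = FALSE]
      for (r in seq_len(nrow(take))) {
        b <- take[r, ]
        crop <- img[b$y + seq_len(b$h), b$x + seq_len(b$w), drop = FALSE]
        mined[[length(mined) + 1]] <- resize_bilinear(crop, object$base_window,
                                                      object$base_window)
        if (length(mined) >= need) return(mined)
      }
    }
    if (scanned >= budget) break
  }
  mined
}
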