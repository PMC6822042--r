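#' @name features
#' @title Haar-like and local-binary-pattern feature primitives
#'
#' @description
#' The cascade consumes two feature families, both computable in constant
#' time from an integral image:
#'
#' * **Haar-like features** — signed differences of pixel sums over
#'   adjacent rectangles. Five layouts are supported: two rectangles side
#'   by side (`"h2"`), two stacked (`"v2"`), three side by side (`"h3"`),
#'   three stacked (`"v3"`), and a 2x2 checkerboard (`"d4"`). For
#'   two-rectangle layouts the first (left/top) rectangle is the positive
#'   region; for three-rectangle layouts the middle rectangle carries
#'   weight +2 against -1 outer rectangles, so positive and negative
#'   weighted areas balance and a constant image scores 0; for the
#'   checkerboard the top-left/bottom-right pair is positive. The raw
#'   weighted difference is divided by the total pixel area of the
#'   feature so values are comparable across scales. There is no
#'   per-window variance normalization.
#' * **Local binary patterns** — an 8-bit code recording, for each of the
#'   8 neighbors of a center (pixels for [lbp_code()], block means for the
#'   multi-block [mb_lbp_code()]), whether the neighbor is at least as
#'   bright as the center. Bits are ordered clockwise from the top-left
#'   neighbor, most significant bit first; ties (neighbor equal to center)
#'   set the bit.
#'
#' Feature anchors live in 0-based half-open coordinates relative to the
#' base window. When a feature is evaluated at scale `s`, each rectangle
#' boundary is scaled and rounded to the nearest integer — the identical
#' rule is used by the detector and by any oracle, so results are
#' bit-reproducible.
NULL

#' Construct a Haar-like feature
#'
#' @param kind One of `"h2"`, `"v2"`, `"h3"`, `"v3"`, `"d4"` (see
#'   [features]).
#' @param x,y,w,h Anchor rectangle relative to the base window (0-based,
#'   half-open). `w` must be divisible by 2 (`h2`, `d4`) or 3 (`h3`);
#'   `h` likewise for the vertical kinds.
#' @return A list of class `"haar_feature"`.
#' @export
haar_feature <- function(kind, x, y, w, h) {
  kind <- match.arg(kind, c("h2", "v2", "h3", "v3", "d4"))
  ok <- switch(kind,
    h2 = w %% 2 == 0,
    v2 = h %% 2 == 0,
    h3 = w %% 3 == 0,
    v3 = h %% 3 == 0,
    d4 = w %% 2 == 0 && h %% 2 == 0)
  if (!ok) stop("anchor dimensions do not admit an exact ", kind, " subdivision")
  if (w <= 0 || h <= 0 || x < 0 || y < 0) stop("invalid anchor rectangle")
  structure(list(family = "haar", kind = kind,
                 x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)),
            class = "haar_feature")
}

#' Construct a multi-block LBP feature
#'
#' The block rectangle is divided into a 3x3 grid of sub-blocks; the code
#' compares the mean intensity of the center sub-block with its 8
#' neighbors.
#'
#' @param x,y,w,h Block rectangle relative to the base window; `w` and `h`
#'   must be divisible by 3.
#' @return A list of class `"lbp_feature"`.
#' @export
lbp_feature <- function(x, y, w, h) {
  if (w %% 3 != 0 || h %% 3 != 0) stop("block width and height must be divisible by 3")
  if (w <= 0 || h <= 0 || x < 0 || y < 0) stop("invalid block rectangle")
  structure(list(family = "lbp",
                 x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)),
            class = "lbp_feature")
}

# scaled rectangle decomposition of a Haar feature: boundaries are scaled
# then rounded, so adjacent rectangles always tile the anchor exactly
haar_geometry <- function(f, scale = 1) {
  xb2 <- function(k) round((f$x + f$w * (0:k) / k) * scale)
  yb2 <- function(k) round((f$y + f$h * (0:k) / k) * scale)
  g <- switch(f$kind,
    h2 = list(xb = xb2(2), yb = yb2(1),
              sign = matrix(c(1, -1), 1, 2)),
    v2 = list(xb = xb2(1), yb = yb2(2),
              sign = matrix(c(1, -1), 2, 1)),
    h3 = list(xb = xb2(3), yb = yb2(1),
              sign = matrix(c(-1, 2, -1), 1, 3)),
    v3 = list(xb = xb2(1), yb = yb2(3),
              sign = matrix(c(-1, 2, -1), 3, 1)),
    d4 = list(xb = xb2(2), yb = yb2(2),
              sign = matrix(c(1, -1, -1, 1), 2, 2)))
  rects <- list()
  area <- 0
  for (i in seq_len(nrow(g$sign))) {
    for (j in seq_len(ncol(g$sign))) {
      x1 <- g$xb[j]; x2 <- g$xb[j + 1]
      y1 <- g$yb[i]; y2 <- g$yb[i + 1]
      rects[[length(rects) + 1]] <- list(x1 = x1, x2 = x2, y1 = y1, y2 = y2,
                                         sign = g$sign[i, j])
      area <- area + (x2 - x1) * (y2 - y1)
    }
  }
  list(rects = rects, area = area)
}

#' Evaluate a Haar feature on an integral image
#'
#' @param ii Integral image.
#' @param f A [haar_feature()].
#' @param window_origin `c(x, y)` of the window's top-left corner (0-based).
#' @param scale Window scale (>= 1 during detection; 1 during training).
#' @return The area-normalized signed rectangle-sum difference.
#' @export
haar_value <- function(ii, f, window_origin = c(0, 0), scale = 1) {
  v <- haar_values_at(ii, f, window_origin[1], window_origin[2], scale)
  v[1]
}

# vectorized over window origins (ox, oy equal-length vectors)
haar_values_at <- function(ii, f, ox, oy, scale = 1) {
  g <- haar_geometry(f, scale)
  h <- nrow(ii) - 1; w <- ncol(ii) - 1
  acc <- numeric(length(ox))
  for (r in g$rects) {
    if (any(ox + r$x2 > w) || any(oy + r$y2 > h) ||
        any(ox + r$x1 < 0) || any(oy + r$y1 < 0)) {
      stop("scaled feature rectangle out of image bounds")
    }
    s <- ii[cbind(oy + r$y2 + 1, ox + r$x2 + 1)] -
         ii[cbind(oy + r$y1 + 1, ox + r$x2 + 1)] -
         ii[cbind(oy + r$y2 + 1, ox + r$x1 + 1)] +
         ii[cbind(oy + r$y1 + 1, ox + r$x1 + 1)]
    acc <- acc + r$sign * s
  }
  if (g$area <= 0) stop("degenerate scaled feature (zero area)")
  acc / g$area
}

#' Pixel-level local binary pattern code
#'
#' @param img Grayscale image matrix.
#' @param center `c(row, col)` of the center pixel, 1-based; all 8
#'   neighbors must be inside the image.
#' @return Integer code in \[0, 255\].
#' @export
lbp_code <- function(img, center) {
  r <- center[1]; c0 <- center[2]
  if (r < 2 || c0 < 2 || r > nrow(img) - 1 || c0 > ncol(img) - 1) {
    stop("center pixel must have all 8 neighbors in bounds")
  }
  cv <- img[r, c0]
  nb <- c(img[r - 1, c0 - 1], img[r - 1, c0], img[r - 1, c0 + 1],
          img[r, c0 + 1], img[r + 1, c0 + 1], img[r + 1, c0],
          img[r + 1, c0 - 1], img[r, c0 - 1])
  bits <- as.integer(nb >= cv)
  sum(bits * 2^(7:0))
}

# clockwise-from-top-left ordering of the 8 neighbor blocks in a 3x3 grid,
# as (row, col) pairs (center is (2, 2))
.lbp_neighbor_order <- cbind(
  row = c(1, 1, 1, 2, 3, 3, 3, 2),
  col = c(1, 2, 3, 3, 3, 2, 1, 1))

#' Multi-block LBP code from an integral image
#'
#' Applies the same comparison rule as [lbp_code()] to the mean intensities
#' of the 9 sub-blocks of the feature's 3x3 grid. With a 3x3-pixel block
#' (1-pixel sub-blocks) this reduces exactly to [lbp_code()] at the grid
#' center.
#'
#' @param ii Integral image.
#' @param f An [lbp_feature()].
#' @param window_origin `c(x, y)` of the window origin (0-based).
#' @param scale Window scale.
#' @return Integer code in \[0, 255\].
#' @export
mb_lbp_code <- function(ii, f, window_origin = c(0, 0), scale = 1) {
  v <- mb_lbp_codes_at(ii, f, window_origin[1], window_origin[2], scale)
  v[1]
}

# vectorized over window origins
mb_lbp_codes_at <- function(ii, f, ox, oy, scale = 1) {
  xb <- round((f$x + f$w * (0:3) / 3) * scale)
  yb <- round((f$y + f$h * (0:3) / 3) * scale)
  h <- nrow(ii) - 1; w <- ncol(ii) - 1
  if (any(ox + xb[4] > w) || any(oy + yb[4] > h) ||
      any(ox + xb[1] < 0) || any(oy + yb[1] < 0)) {
    stop("scaled 3x3 block grid out of image bounds")
  }
  if (any(diff(xb) <= 0) || any(diff(yb) <= 0)) {
    stop("degenerate scaled sub-blocks (zero size)")
  }
  block_mean <- function(i, j) {
    x1 <- xb[j]; x2 <- xb[j + 1]; y1 <- yb[i]; y2 <- yb[i + 1]
    s <- ii[cbind(oy + y2 + 1, ox + x2 + 1)] -
         ii[cbind(oy + y1 + 1, ox + x2 + 1)] -
         ii[cbind(oy + y2 + 1, ox + x1 + 1)] +
         ii[cbind(oy + y1 + 1, ox + x1 + 1)]
    s / ((x2 - x1) * (y2 - y1))
  }
  ctr <- block_mean(2, 2)
  code <- integer(length(ox))
  for (k in 1:8) {
    nb <- block_mean(.lbp_neighbor_order[k, 1], .lbp_neighbor_order[k, 2])
    code <- code + as.integer(nb >= ctr) * 2L^(8L - k)
  }
  code
}

#' Enumerate a pool of Haar features for a base window
#'
#' Anchors are enumerated on a stride grid over positions and sizes; if the
#' enumeration exceeds `max_features` a deterministic seeded subsample is
#' drawn, keeping training at desk scale.
#'
#' @param base Base window side in pixels (default 24).
#' @param stride Position stride in pixels.
#' @param size_step Size stride in pixels.
#' @param min_size Minimum anchor side.
#' @param max_features Cap on pool size (`Inf` for the full enumeration).
#' @param seed Seed for the subsample draw.
#' @return A list of [haar_feature()] objects.
#' @export
haar_feature_pool <- function(base = 24L, stride = 2L, size_step = 2L,
                              min_size = 4L, max_features = Inf, seed = 1L) {
  pool <- list()
  for (kind in c("h2", "v2", "h3", "v3", "d4")) {
    for (w in seq(min_size, base, by = size_step)) {
      for (h in seq(min_size, base, by = size_step)) {
        ok <- switch(kind,
          h2 = w %% 2 == 0, v2 = h %% 2 == 0,
          h3 = w %% 3 == 0, v3 = h %% 3 == 0,
          d4 = w %% 2 == 0 && h %% 2 == 0)
        if (!ok) next
        for (x in seq(0, base - w, by = stride)) {
          for (y in seq(0, base - h, by = stride)) {
            pool[[length(pool) + 1]] <- haar_feature(kind, x, y, w, h)
          }
        }
      }
    }
  }
  subsample_pool(pool, max_features, seed)
}

#' Enumerate a pool of multi-block LBP features for a base window
#'
#' @inheritParams haar_feature_pool
#' @return A list of [lbp_feature()] objects (block sizes are multiples
#'   of 3).
#' @export
lbp_feature_pool <- function(base = 24L, stride = 2L, max_features = Inf,
                             seed = 1L) {
  pool <- list()
  for (w in seq(3, base, by = 3)) {
    for (h in seq(3, base, by = 3)) {
      for (x in seq(0, base - w, by = stride)) {
        for (y in seq(0, base - h, by = stride)) {
          pool[[length(pool) + 1]] <- lbp_feature(x, y, w, h)
        }
      }
    }
  }
  subsample_pool(pool, max_features, seed)
}

subsample_pool <- function(pool, max_features, seed) {
  if (length(pool) > max_features) {
    idx <- with_seed(seed, sample.int(length(pool), max_features))
    pool <- pool[sort(idx)]
  }
  pool
}

# feature values for a stack of base-window samples, given as a 3-D array
# of integral images (n x (base+1) x (base+1))
eval_feature_samples <- function(arr, f) {
  rs <- function(x1, x2, y1, y2) {
    arr[, y2 + 1, x2 + 1] - arr[, y1 + 1, x2 + 1] -
      arr[, y2 + 1, x1 + 1] + arr[, y1 + 1, x1 + 1]
  }
  if (f$family == "haar") {
    g <- haar_geometry(f, 1)
    acc <- numeric(dim(arr)[1])
    for (r in g$rects) acc <- acc + r$sign * rs(r$x1, r$x2, r$y1, r$y2)
    return(acc / g$area)
  }
  xb <- f$x + f$w * (0:3) / 3
  yb <- f$y + f$h * (0:3) / 3
  bm <- function(i, j) {
    rs(xb[j], xb[j + 1], yb[i], yb[i + 1]) /
      ((xb[j + 1] - xb[j]) * (yb[i + 1] - yb[i]))
  }
  ctr <- bm(2, 2)
  code <- integer(dim(arr)[1])
  for (k in 1:8) {
    nb <- bm(.lbp_neighbor_order[k, 1], .lbp_neighbor_order[k, 2])
    code <- code + as.integer(nb >= ctr) * 2L^(8L - k)
  }
  code
}
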