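# Independent oracles used across the suite. These deliberately avoid the
# package's integral-image path: sums are direct pixel loops, IoU is pixel
# rasterization, LBP bits are enumerated by hand.

# direct pixel-loop rectangle sum (0-based half-open box)
brute_rect_sum <- function(img, x, y, w, h) {
  s <- 0
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      s <- s + img[y + r, x + c]
    }
  }
  s
}

# brute-force Haar value: recompute the rounded scaled boundaries from the
# published subdivision rule, then sum pixels directly
brute_haar_value <- function(img, f, ox = 0, oy = 0, scale = 1) {
  xb <- function(k) round((f$x + f$w * (0:k) / k) * scale) + ox
  yb <- function(k) round((f$y + f$h * (0:k) / k) * scale) + oy
  spec <- switch(f$kind,
    h2 = list(x = xb(2), y = yb(1), s = matrix(c(1, -1), 1, 2)),
    v2 = list(x = xb(1), y = yb(2), s = matrix(c(1, -1), 2, 1)),
    h3 = list(x = xb(3), y = yb(1), s = matrix(c(-1, 2, -1), 1, 3)),
    v3 = list(x = xb(1), y = yb(3), s = matrix(c(-1, 2, -1), 3, 1)),
    d4 = list(x = xb(2), y = yb(2), s = matrix(c(1, -1, -1, 1), 2, 2)))
  acc <- 0
  area <- 0
  for (i in seq_len(nrow(spec$s))) {
    for (j in seq_len(ncol(spec$s))) {
      x1 <- spec$x[j]; x2 <- spec$x[j + 1]
      y1 <- spec$y[i]; y2 <- spec$y[i + 1]
      acc <- acc + spec$s[i, j] * brute_rect_sum(img, x1, y1, x2 - x1, y2 - y1)
      area <- area + (x2 - x1) * (y2 - y1)
    }
  }
  acc / area
}

# brute-force multi-block LBP: block means by pixel loops, bits by hand
brute_mb_lbp <- function(img, f, ox = 0, oy = 0, scale = 1) {
  xb <- round((f$x + f$w * (0:3) / 3) * scale) + ox
  yb <- round((f$y + f$h * (0:3) / 3) * scale) + oy
  means <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      w <- xb[j + 1] - xb[j]; h <- yb[i + 1] - yb[i]
      means[i, j] <- brute_rect_sum(img, xb[j], yb[i], w, h) / (w * h)
    }
  }
  order_rc <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3),
                    c(3, 3), c(3, 2), c(3, 1), c(2, 1))
  code <- 0
  for (k in 1:8) {
    if (means[order_rc[k, 1], order_rc[k, 2]] >= means[2, 2]) {
      code <- code + 2^(8 - k)
    }
  }
  code
}

# pixel-rasterization IoU (integer boxes)
raster_iou <- function(a, b) {
  xmax <- max(a$x + a$w, b$x + b$w)
  ymax <- max(a$y + a$h, b$y + b$h)
  ma <- matrix(FALSE, ymax, xmax)
  mb <- matrix(FALSE, ymax, xmax)
  ma[a$y + seq_len(a$h), a$x + seq_len(a$w)] <- TRUE
  mb[b$y + seq_len(b$h), b$x + seq_len(b$w)] <- TRUE
  sum(ma & mb) / sum(ma | mb)
}

# exhaustive decision-stump search over every threshold/polarity
brute_stump <- function(v, y, w) {
  cand <- sort(unique(c(v - 0.5, v + 0.5, (v[-1] + v[-length(v)]) / 2)))
  best <- list(err = Inf)
  for (t in cand) {
    for (p in c(1, -1)) {
      pred <- ifelse(p * v < p * t, 1, -1)
      err <- sum(w[pred != y])
      if (err < best$err) best <- list(threshold = t, polarity = p, err = err)
    }
  }
  best
}

rand_box <- function(max_xy = 20, max_wh = 15) {
  bbox(sample.int(max_xy, 1) - 1, sample.int(max_xy, 1) - 1,
       sample.int(max_wh, 1), sample.int(max_wh, 1))
}
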