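#' Classify one window with a cascade
#'
#' A window is accepted iff every stage's weighted weak-classifier vote
#' reaches that stage's threshold; evaluation short-circuits at the first
#' rejecting stage, which is what makes cascades fast on background.
#'
#' @param object A fitted [cascade_detector()].
#' @param ii Integral image of the frame.
#' @param origin `c(x, y)` of the window's top-left corner (0-based).
#' @param scale Window scale relative to the base window.
#' @return `TRUE` if the window passes every stage.
#' @export
classify_window <- function(object, ii, origin, scale = 1) {
  for (st in object$stages) {
    sc <- 0
    for (wk in st$weaks) {
      f <- object$pool[[wk$feature]]
      col <- if (f$family == "haar") {
        haar_values_at(ii, f, origin[1], origin[2], scale)
      } else {
        mb_lbp_codes_at(ii, f, origin[1], origin[2], scale)
      }
      sc <- sc + wk$alpha * (if (wk$type == "stump") {
        ifelse(wk$polarity * col < wk$polarity * wk$threshold, 1, -1)
      } else {
        wk$lut[col + 1L]
      })
    }
    if (sc < st$threshold) return(FALSE)
  }
  TRUE
}

# multiscale raw window scan: every accepted window before grouping.
# Returns a data frame of boxes with attribute n_windows (total scanned).
detect_raw <- function(object, img, scan = object$scan, stages = NULL) {
  ii <- integral_image(img)
  base <- object$base_window
  h <- nrow(img); w <- ncol(img)
  use_stages <- if (is.null(stages)) object$stages else object$stages[seq_len(stages)]
  out_x <- integer(0); out_y <- integer(0); out_w <- integer(0)
  n_windows <- 0
  s <- 1
  seen <- integer(0)
  repeat {
    win <- round(base * s)
    if (win > min(h, w) || win > scan$max_window) break
    if (!(win %in% seen)) {
      seen <- c(seen, win)
      step <- max(1, round(scan$step * s))
      oxs <- seq(0L, w - win, by = step)
      oys <- seq(0L, h - win, by = step)
      ox <- rep(oxs, times = length(oys))
      oy <- rep(oys, each = length(oxs))
      n_windows <- n_windows + length(ox)
      keep <- seq_along(ox)
      for (st in use_stages) {
        if (length(keep) == 0) break
        sc <- numeric(length(keep))
        for (wk in st$weaks) {
          f <- object$pool[[wk$feature]]
          col <- if (f$family == "haar") {
            haar_values_at(ii, f, ox[keep], oy[keep], s)
          } else {
            mb_lbp_codes_at(ii, f, ox[keep], oy[keep], s)
          }
          sc <- sc + wk$alpha * (if (wk$type == "stump") {
            ifelse(wk$polarity * col < wk$polarity * wk$threshold, 1, -1)
          } else {
            wk$lut[col + 1L]
          })
        }
        keep <- keep[sc >= st$threshold]
      }
      if (length(keep) > 0) {
        out_x <- c(out_x, ox[keep]); out_y <- c(out_y, oy[keep])
        out_w <- c(out_w, rep(win, length(keep)))
      }
    }
    s <- s * scan$scale_factor
  }
  res <- data.frame(x = out_x, y = out_y, w = out_w, h = out_w)
  attr(res, "n_windows") <- n_windows
  res
}

#' Group raw detection windows
#'
#' Raw accepted windows are partitioned into connected components under
#' pairwise IoU >= 0.5; components with fewer than `min_neighbors` members
#' are discarded (isolated hits are usually noise), and each surviving
#' component is replaced by its coordinate-wise mean box, rounded.
#'
#' @param raw Data frame of boxes (columns `x`, `y`, `w`, `h`) or list of
#'   [bbox()].
#' @param min_neighbors Minimum component size to survive.
#' @return Data frame of grouped boxes with a `score` column holding the
#'   number of raw windows merged into each box.
#' @export
group_detections <- function(raw, min_neighbors = 2L) {
  raw <- boxes_df(raw)
  n <- nrow(raw)
  empty <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0), score = integer(0))
  if (n == 0) return(empty)
  # connected components of the IoU >= 0.5 similarity graph. IoU >= 0.5
  # forces an area ratio of at least 0.5, so boxes are sorted by area and
  # each is tested only against the area-compatible candidates below it;
  # the exact IoU check then prunes the rest.
  ord <- order(raw$w * raw$h)
  rx <- raw$x[ord]; ry <- raw$y[ord]
  rw <- raw$w[ord]; rh <- raw$h[ord]
  x2 <- rx + rw; y2 <- ry + rh
  area <- rw * rh
  edges <- vector("list", n)
  for (j in seq_len(n)) {
    lo <- findInterval(area[j] / 2 - 1e-9, area) + 1L
    if (lo >= j) next
    cand <- lo:(j - 1L)
    ix <- pmax(0, pmin(x2[cand], x2[j]) - pmax(rx[cand], rx[j]))
    iy <- pmax(0, pmin(y2[cand], y2[j]) - pmax(ry[cand], ry[j]))
    inter <- ix * iy
    nb <- cand[inter / (area[cand] + area[j] - inter) >= 0.5]
    if (length(nb)) edges[[j]] <- rbind(ord[nb], ord[j])
  }
  el <- do.call(cbind, edges)
  g <- igraph::make_graph(if (is.null(el)) integer(0) else as.vector(el),
                          n = n, directed = FALSE)
  comp <- as.integer(igraph::components(g)$membership)
  sums <- rowsum(cbind(raw$x, raw$y, raw$w, raw$h, 1), comp)
  cnt <- sums[, 5]
  ok <- cnt >= min_neighbors
  if (!any(ok)) return(empty)
  out <- data.frame(x = round(sums[ok, 1] / cnt[ok]),
                    y = round(sums[ok, 2] / cnt[ok]),
                    w = round(sums[ok, 3] / cnt[ok]),
                    h = round(sums[ok, 4] / cnt[ok]),
                    score = as.integer(cnt[ok]))
  rownames(out) <- NULL
  # reading order: top-to-bottom, then left-to-right
  out[order(out$y, out$x), , drop = FALSE]
}

#' Detect objects in a frame
#'
#' Slides the base window over the frame at scales
#' `base * scale_factor^k`, with the pixel step scaled proportionally,
#' classifies every window with the cascade, and groups the accepted
#' windows with [group_detections()]. Frames smaller than the base window
#' yield an empty result with a message.
#'
#' @param object A fitted [cascade_detector()].
#' @param img Grayscale frame matrix.
#' @param scan A [scan_config()]; defaults to the one stored on the model.
#' @param frame_id Identifier attached to the result rows.
#' @return Data frame of detections: `frame_id`, `x`, `y`, `w`, `h`,
#'   `score` (grouped-neighbor count), in reading order.
#' @export
detect <- function(object, img, scan = object$scan, frame_id = NA) {
  stopifnot(inherits(object, "cascade_detector"))
  empty <- data.frame(frame_id = character(0), x = numeric(0),
                      y = numeric(0), w = numeric(0), h = numeric(0),
                      score = integer(0))
  if (min(dim(img)) < object$base_window) {
    message("frame smaller than the base window; no detections possible")
    return(empty)
  }
  raw <- detect_raw(object, img, scan)
  grouped <- group_detections(raw, scan$min_neighbors)
  if (nrow(grouped) == 0) return(empty)
  cbind(data.frame(frame_id = rep(frame_id, nrow(grouped))), grouped)
}

#' @rdname detect
#' @param newdata A grayscale frame matrix, or a (possibly named) list of
#'   frames; names become `frame_id`s.
#' @param ... Unused.
#' @export
predict.cascade_detector <- function(object, newdata, scan = object$scan,
                                     ...) {
  if (is.matrix(newdata)) {
    return(detect(object, newdata, scan, frame_id = "frame_1"))
  }
  ids <- names(newdata) %||% sprintf("frame_%d", seq_along(newdata))
  do.call(rbind, lapply(seq_along(newdata), function(i) {
    detect(object, newdata[[i]], scan, frame_id = ids[i])
  }))
}
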