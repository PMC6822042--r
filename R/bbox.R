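#' Axis-aligned bounding box
#'
#' Boxes use 0-based pixel coordinates with a half-open convention: a box
#' covers columns `[x, x + w)` and rows `[y, y + h)`. This single convention
#' is shared by the scene generator, the detector and the evaluator, so no
#' off-by-one ambiguity can creep in between modules. Collections of boxes
#' are plain data frames with columns `x`, `y`, `w`, `h`.
#'
#' @param x,y Integer top-left corner (0-based).
#' @param w,h Positive integer width and height in pixels.
#' @return A list of class `"bbox"` with fields `x`, `y`, `w`, `h`.
#' @examples
#' b <- bbox(2, 3, 10, 5)
#' iou(b, b)
#' @export
bbox <- function(x, y, w, h) {
  x <- as.numeric(x); y <- as.numeric(y)
  w <- as.numeric(w); h <- as.numeric(h)
  stopifnot(length(x) == 1, length(y) == 1, length(w) == 1, length(h) == 1)
  if (!all(is.finite(c(x, y, w, h)))) stop("bbox fields must be finite")
  if (w <= 0 || h <= 0) stop("bbox width and height must be positive")
  if (x < 0 || y < 0) stop("bbox origin must be non-negative")
  structure(list(x = x, y = y, w = w, h = h), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox x=%g y=%g w=%g h=%g>\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

# accept a bbox, a named list, or a 1-row data frame
as_box <- function(b) {
  if (inherits(b, "bbox")) return(b)
  if (is.data.frame(b)) {
    stopifnot(nrow(b) == 1)
    return(bbox(b$x, b$y, b$w, b$h))
  }
  bbox(b$x, b$y, b$w, b$h)
}

# data frame of boxes (possibly 0 rows) from a list of bbox / row df
boxes_df <- function(boxes) {
  if (is.data.frame(boxes)) {
    if (nrow(boxes) == 0) {
      return(data.frame(x = numeric(0), y = numeric(0),
                        w = numeric(0), h = numeric(0)))
    }
    return(boxes[, c("x", "y", "w", "h"), drop = FALSE])
  }
  if (length(boxes) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0)))
  }
  do.call(rbind, lapply(boxes, function(b) {
    b <- as_box(b)
    data.frame(x = b$x, y = b$y, w = b$w, h = b$h)
  }))
}

#' Intersection over union of two boxes
#'
#' The matching statistic of the evaluation: area of overlap divided by
#' area of union, computed under the half-open pixel convention. Disjoint
#' boxes score 0; identical boxes score 1.
#'
#' @param a,b Boxes (`bbox`, named list, or 1-row data frame).
#' @return A fraction in \[0, 1\].
#' @export
iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  inter / union
}

#' Pairwise IoU matrix between two box sets
#'
#' @param a,b Data frames with columns `x`, `y`, `w`, `h` (rows are boxes).
#' @return A `nrow(a)` by `nrow(b)` numeric matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  a <- boxes_df(a); b <- boxes_df(b)
  na <- nrow(a); nb <- nrow(b)
  m <- matrix(0, na, nb)
  if (na == 0 || nb == 0) return(m)
  ax2 <- a$x + a$w; ay2 <- a$y + a$h
  bx2 <- b$x + b$w; by2 <- b$y + b$h
  for (j in seq_len(nb)) {
    ix <- pmax(0, pmin(ax2, bx2[j]) - pmax(a$x, b$x[j]))
    iy <- pmax(0, pmin(ay2, by2[j]) - pmax(a$y, b$y[j]))
    inter <- ix * iy
    m[, j] <- inter / (a$w * a$h + b$w[j] * b$h[j] - inter)
  }
  m
}

# area of b inside region, in pixels
bbox_inside_area <- function(b, region) {
  b <- as_box(b); region <- as_box(region)
  ix <- max(0, min(b$x + b$w, region$x + region$w) - max(b$x, region$x))
  iy <- max(0, min(b$y + b$h, region$y + region$h) - max(b$y, region$y))
  ix * iy
}

# clip b to region; NULL if empty
bbox_clip <- function(b, region) {
  b <- as_box(b); region <- as_box(region)
  x1 <- max(b$x, region$x); y1 <- max(b$y, region$y)
  x2 <- min(b$x + b$w, region$x + region$w)
  y2 <- min(b$y + b$h, region$y + region$h)
  if (x2 <= x1 || y2 <= y1) return(NULL)
  bbox(x1, y1, x2 - x1, y2 - y1)
}
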