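#' Convert an RGB image to grayscale
#'
#' Collapses a 3-channel image to a single intensity plane using the video
#' luma weights 0.299/0.587/0.114, the usual convention for CCTV-derived
#' imagery. A matrix (already grayscale) or an array whose three channels
#' are identical passes through unchanged.
#'
#' @param img Numeric matrix (height x width) or array (height x width x 3)
#'   with finite values in \[0, 255\].
#' @return A numeric matrix of intensities in \[0, 255\].
#' @export
to_grayscale <- function(img) {
  if (!all(is.finite(img))) stop("image contains non-finite pixel values")
  if (is.matrix(img)) {
    if (min(img) < 0 || max(img) > 255) stop("pixel values outside [0, 255]")
    return(img)
  }
  if (!(is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3)) {
    stop("expected a matrix or a height x width x 3 array")
  }
  if (min(img) < 0 || max(img) > 255) stop("pixel values outside [0, 255]")
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  # 1-pixel-wide inputs drop to vectors; restore the matrix shape
  matrix(g, dim(img)[1], dim(img)[2])
}

#' Integral image (summed-area table)
#'
#' Builds the cumulative-sum table that lets any axis-aligned rectangle sum
#' be read off in four lookups: entry `(r, c)` (1-based) holds the sum of
#' all pixels with row index `< r` and column index `< c`, so the table is
#' `(height + 1) x (width + 1)` with a zero first row and column.
#'
#' @param img Grayscale image matrix.
#' @return Numeric matrix of size `(nrow(img) + 1) x (ncol(img) + 1)`.
#' @export
integral_image <- function(img) {
  if (!is.matrix(img)) stop("expected a grayscale image matrix")
  if (!all(is.finite(img))) stop("image contains non-finite pixel values")
  h <- nrow(img); w <- ncol(img)
  ii <- matrix(0, h + 1, w + 1)
  ii[-1, -1] <- t(apply(apply(img, 2, cumsum), 1, cumsum))
  ii
}

#' Rectangle sum from an integral image
#'
#' @param ii Integral image from [integral_image()].
#' @param r A [bbox()] (0-based, half-open) fully inside the image.
#' @return The sum of pixels covered by `r`.
#' @export
rect_sum <- function(ii, r) {
  r <- as_box(r)
  h <- nrow(ii) - 1; w <- ncol(ii) - 1
  if (r$x + r$w > w || r$y + r$h > h) stop("rectangle out of image bounds")
  ii[r$y + r$h + 1, r$x + r$w + 1] - ii[r$y + 1, r$x + r$w + 1] -
    ii[r$y + r$h + 1, r$x + 1] + ii[r$y + 1, r$x + 1]
}

#' Read an image frame from PNG or JPEG
#'
#' Returns intensities on the 0-255 scale; color frames are collapsed with
#' [to_grayscale()] when `grayscale = TRUE`.
#'
#' @param path File path (PNG; JPEG is not produced by this package but a
#'   `.png` written elsewhere is fine).
#' @param grayscale Collapse color input to one channel? Default `TRUE`.
#' @return Matrix (grayscale) or array (color) of intensities in \[0, 255\].
#' @export
read_frame <- function(path, grayscale = TRUE) {
  px <- png::readPNG(path)
  px <- px * 255
  if (length(dim(px)) == 3) {
    if (dim(px)[3] >= 3) px <- px[, , 1:3] else px <- px[, , 1]
  }
  if (grayscale) px <- to_grayscale(px)
  px
}

#' Write a grayscale frame as 8-bit PNG
#'
#' @param img Intensity matrix in \[0, 255\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(img, path) {
  img <- pmin(pmax(img, 0), 255)
  png::writePNG(round(img) / 255, target = path)
  invisible(path)
}

# Deterministic bilinear resize; exact rounding here must match between the
# trainer's letterboxing and the hard-negative miner, which is why it is
# spelled out rather than delegated.
resize_bilinear <- function(img, out_h, out_w) {
  in_h <- nrow(img); in_w <- ncol(img)
  if (in_h == out_h && in_w == out_w) return(img)
  # sample at pixel centers
  ys <- (seq_len(out_h) - 0.5) * in_h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * in_w / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), in_h - 1)
  x0 <- pmin(pmax(floor(xs), 0), in_w - 1)
  y1 <- pmin(y0 + 1, in_h - 1)
  x1 <- pmin(x0 + 1, in_w - 1)
  fy <- pmin(pmax(ys - y0, 0), 1)
  fx <- pmin(pmax(xs - x0, 0), 1)
  a <- img[y0 + 1, x0 + 1, drop = FALSE]
  b <- img[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- img[y1 + 1, x0 + 1, drop = FALSE]
  d <- img[y1 + 1, x1 + 1, drop = FALSE]
  wfy <- matrix(fy, out_h, out_w)
  wfx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - wfy) * (1 - wfx) + b * (1 - wfy) * wfx +
    c_ * wfy * (1 - wfx) + d * wfy * wfx
}

# Pad a patch to a square (centered, filled with its median intensity) and
# resize to size x size. Preserves aspect ratio: positive crops of highly
# variable shape are letterboxed, never distorted.
letterbox <- function(img, size) {
  h <- nrow(img); w <- ncol(img)
  s <- max(h, w)
  if (h != w) {
    fill <- stats::median(img)
    sq <- matrix(fill, s, s)
    oy <- floor((s - h) / 2); ox <- floor((s - w) / 2)
    sq[oy + seq_len(h), ox + seq_len(w)] <- img
    img <- sq
  }
  resize_bilinear(img, size, size)
}
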