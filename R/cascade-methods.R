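#' @export
print.cascade_detector <- function(x, ...) {
  cat("Boosted cascade detector\n")
  cat(sprintf("  feature family : %s\n", x$feature_family))
  cat(sprintf("  base window    : %d x %d px\n", x$base_window, x$base_window))
  cat(sprintf("  stages         : %d (%d weak classifiers)\n",
              length(x$stages),
              sum(vapply(x$stages, function(s) length(s$weaks), integer(1)))))
  cat(sprintf("  training FPR   : %.4g (product of per-stage rates)\n",
              prod(x$log$achieved_fpr)))
  invisible(x)
}

#' Summarize a fitted cascade
#'
#' @param object A [cascade_detector()].
#' @param ... Unused.
#' @return A data frame, one row per stage, with the number of weak
#'   classifiers and the achieved true/false-positive rates on that
#'   stage's training sets.
#' @export
summary.cascade_detector <- function(object, ...) {
  out <- object$log
  out$cum_fpr <- cumprod(out$achieved_fpr)
  class(out) <- c("summary.cascade_detector", "data.frame")
  out
}

#' @export
print.summary.cascade_detector <- function(x, ...) {
  cat("Per-stage training rates (negatives are re-mined per stage):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot per-stage training rates of a cascade
#'
#' @param x A [cascade_detector()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cascade_detector <- function(x, ...) {
  lg <- x$log
  graphics::plot(lg$stage, lg$achieved_fpr, type = "b", pch = 19,
                 ylim = c(0, max(0.25, max(lg$achieved_fpr))),
                 xlab = "stage", ylab = "rate on stage training sets", ...)
  graphics::lines(lg$stage, 1 - lg$achieved_tpr, type = "b", pch = 1, lty = 2)
  graphics::abline(h = x$config$stage_fpr_target, col = "grey50", lty = 3)
  graphics::legend("topright", bty = "n", pch = c(19, 1), lty = c(1, 2),
                   legend = c("false-positive rate", "1 - true-positive rate"))
  invisible(x)
}

#' Serialize a cascade to JSON
#'
#' Writes a versioned, self-contained description of the model (feature
#' family, base window, feature pool, stages with rules and thresholds,
#' scan defaults). [read_cascade()] restores an equivalent object;
#' identical training inputs and seed produce byte-identical files.
#'
#' @param object A [cascade_detector()].
#' @param path Output file path, or `NULL` to return the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_cascade <- function(object, path = NULL) {
  stopifnot(inherits(object, "cascade_detector"))
  payload <- list(
    schema = "birdcascade/cascade",
    schema_version = 1L,
    feature_family = object$feature_family,
    base_window = object$base_window,
    scan = unclass(object$scan),
    config = unclass(object$config),
    pool = lapply(object$pool, unclass),
    stages = lapply(object$stages, function(s) {
      list(threshold = s$threshold, achieved_fpr = s$achieved_fpr,
           achieved_tpr = s$achieved_tpr,
           weaks = lapply(s$weaks, function(wk) wk[setdiff(names(wk), "err")]))
    }),
    log = object$log)
  # 17 significant digits: doubles survive the JSON round-trip exactly,
  # so a restored cascade classifies every window identically
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Restore a cascade from JSON
#'
#' @param path File written by [write_cascade()].
#' @return A `"cascade_detector"` object.
#' @export
read_cascade <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(p$schema, "birdcascade/cascade")) {
    stop("not a serialized cascade file")
  }
  pool <- lapply(p$pool, function(f) {
    if (f$family == "haar") {
      haar_feature(f$kind, f$x, f$y, f$w, f$h)
    } else {
      lbp_feature(f$x, f$y, f$w, f$h)
    }
  })
  stages <- lapply(p$stages, function(s) {
    list(weaks = lapply(s$weaks, function(wk) {
      wk$feature <- as.integer(wk$feature)
      if (wk$type == "lut") wk$lut <- as.integer(unlist(wk$lut))
      wk
    }),
    threshold = s$threshold, achieved_fpr = s$achieved_fpr,
    achieved_tpr = s$achieved_tpr, failed = FALSE)
  })
  log <- do.call(rbind, lapply(p$log, as.data.frame))
  structure(list(stages = stages, pool = pool,
                 feature_family = p$feature_family,
                 base_window = as.integer(p$base_window),
                 config = do.call(train_config, p$config),
                 scan = do.call(scan_config, p$scan),
                 log = log, call = NULL),
            class = "cascade_detector")
}
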