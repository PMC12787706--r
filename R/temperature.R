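#' Pixel-wise temporal mean image of a stack
#'
#' @param stack a [thermal_stack()].
#' @return An H x W numeric matrix.
#' @export
temporal_mean_image <- function(stack) {
  stopifnot(inherits(stack, "ThermalStack"))
  rowMeans(stack$frames, dims = 2L)
}

# 8-connected component labeling (iterative flood fill; images are small).
label_components_8 <- function(bw) {
  h <- nrow(bw); w <- ncol(bw)
  lab <- matrix(0L, h, w)
  cur <- 0L
  offs_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  offs_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in which(bw)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      nr <- r + offs_r; nc <- cc + offs_c
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      np <- (nc[ok] - 1L) * h + nr[ok]
      np <- np[bw[np] & lab[np] == 0L]
      if (length(np)) {
        lab[np] <- cur
        queue <- c(queue, np)
      }
    }
  }
  lab
}

#' Segment the hottest facial regions by threshold binarization
#'
#' Binarizes an image (typically the temporal mean of a stack) at a
#' predetermined temperature threshold, labels 8-connected components,
#' drops components smaller than `min_area_px`, and keeps the
#' `keep_components` largest (two by default: the two inner canthi, which
#' nearly coincide with the hottest regions of the face). Either an
#' absolute threshold in degrees (`threshold_c`, matching the
#' predetermined-threshold protocol) or a top-percentile of the image
#' (`threshold_pct`) can be given; the absolute threshold wins when both
#' are set.
#'
#' @param image H x W numeric matrix (e.g. [temporal_mean_image()]).
#' @param threshold_c absolute threshold (image units / degC), or `NULL`.
#' @param threshold_pct percentile of the image used as threshold when no
#'   absolute threshold is given (default 99.5).
#' @param keep_components number of largest components retained.
#' @param min_area_px components smaller than this are dropped.
#' @return An object of class `BinaryMask`: fields `mask` (H x W logical),
#'   `source_threshold` (the threshold value used), `component_count`.
#' @export
segment_hottest <- function(image, threshold_c = NULL, threshold_pct = 99.5,
                            keep_components = 2L, min_area_px = 4L) {
  stopifnot(is.matrix(image), is.numeric(image))
  thr <- if (!is.null(threshold_c)) threshold_c else
    quantile(image, threshold_pct / 100, names = FALSE)
  if (thr > max(image))
    stop("threshold ", format(thr), " exceeds the image maximum; empty mask")
  bw <- image >= thr
  lab <- label_components_8(bw)
  if (max(lab) == 0L) stop("segmentation produced an empty mask")
  areas <- tabulate(lab[lab > 0L])
  keep_ids <- which(areas >= min_area_px)
  if (!length(keep_ids)) stop("all components smaller than min_area_px")
  keep_ids <- keep_ids[order(-areas[keep_ids])]
  keep_ids <- head(keep_ids, keep_components)
  mask <- matrix(lab %in% keep_ids, nrow(image), ncol(image))
  structure(list(mask = mask, source_threshold = thr,
                 component_count = length(keep_ids)),
            class = "BinaryMask")
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("BinaryMask: %d px in %d component(s), threshold %.4g\n",
              sum(x$mask), x$component_count, x$source_threshold))
  invisible(x)
}

mask_indices <- function(stack, mask) {
  stopifnot(inherits(stack, "ThermalStack"), inherits(mask, "BinaryMask"))
  d <- dim(stack$frames)
  if (!all(dim(mask$mask) == d[1:2]))
    stop("mask shape does not match the stack frames")
  idx <- which(mask$mask)
  if (!length(idx)) stop("empty mask")
  idx
}

#' Body temperature over a segmented measurement area
#'
#' The mean over all masked pixels and all frames: the temporal-average
#' temperature of the inner-canthus measurement area.
#'
#' @param stack a [thermal_stack()] of calibrated temperatures.
#' @param mask a [segment_hottest()] mask.
#' @return Scalar temperature (degC).
#' @export
body_temperature <- function(stack, mask) {
  idx <- mask_indices(stack, mask)
  d <- dim(stack$frames)
  flat <- matrix(stack$frames, d[1] * d[2], d[3])
  mean(flat[idx, ])
}

#' Per-frame mean temperature of a masked region
#'
#' The canthus-region time series feeding the pulse path: bandpass at
#' 0.8-1.5 Hz, detect peaks, and convert mean peak intervals to beats per
#' minute (see [estimate_rate()]).
#'
#' @inheritParams body_temperature
#' @param label signal label.
#' @return A [time_series_signal()] with `fs = stack$fps`.
#' @export
canthus_signal <- function(stack, mask, label = "canthus mean") {
  idx <- mask_indices(stack, mask)
  d <- dim(stack$frames)
  flat <- matrix(stack$frames, d[1] * d[2], d[3])
  vals <- colMeans(flat[idx, , drop = FALSE])
  time_series_signal(vals, fs = stack$fps, label = label)
}
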