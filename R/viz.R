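#' Enhance exhaled-CO2 contrast by temporal mean subtraction
#'
#' Subtracts the pixel-wise temporal mean image from every frame, so that
#' the transient absorption of MWIR radiation by exhaled CO2 stands out as
#' dark regions against a near-zero background. With `window = NULL`
#' (default) the global stack mean is used; an odd sliding-window length in
#' frames selects a local-mean variant.
#'
#' @param stack a [thermal_stack()] with at least 2 frames.
#' @param window optional odd integer: sliding temporal window (frames) for
#'   a local-mean subtraction instead of the global mean.
#' @return A [thermal_stack()] of differences with metadata preserved and
#'   the origin note annotated as processed.
#' @export
mean_subtract <- function(stack, window = NULL) {
  stopifnot(inherits(stack, "ThermalStack"))
  nt <- n_frames(stack)
  if (nt < 2L) stop("mean subtraction needs at least 2 frames")
  if (is.null(window)) {
    mu <- rowMeans(stack$frames, dims = 2L)
    out <- stack$frames - as.vector(mu)  # recycles H*W mean over frames
  } else {
    window <- as.integer(window)
    if (window < 3L || window %% 2L == 0L || window > nt)
      stop("`window` must be an odd integer in [3, n_frames]")
    half <- window %/% 2L
    d <- dim(stack$frames)
    flat <- matrix(stack$frames, d[1] * d[2], d[3])
    cs <- cbind(0, t(apply(flat, 1L, cumsum)))
    out <- array(0, d)
    for (t in seq_len(nt)) {
      a <- max(1L, t - half); b <- min(nt, t + half)
      out[, , t] <- stack$frames[, , t] -
        matrix((cs[, b + 1L] - cs[, a]) / (b - a + 1L), d[1], d[2])
    }
  }
  thermal_stack(out, fps = stack$fps, pixel_scale = stack$pixel_scale,
                modality = stack$modality,
                origin_note = paste0(stack$origin_note,
                                     " | mean-subtracted",
                                     if (!is.null(window))
                                       paste0(" (window ", window, ")")))
}

#' Map a stack linearly to [0, 1] for display
#'
#' Computes global percentiles over the whole stack (not per frame, which
#' would destroy temporal contrast), maps them linearly to `[0, 1]` and
#' clips. A constant stack maps to 0.5 everywhere by convention.
#'
#' @param stack a [thermal_stack()].
#' @param low_pct,high_pct percentiles mapped to 0 and 1;
#'   `0 <= low_pct < high_pct <= 100`.
#' @return A [thermal_stack()] with values in `[0, 1]`.
#' @export
normalize_for_display <- function(stack, low_pct = 1, high_pct = 99) {
  stopifnot(inherits(stack, "ThermalStack"))
  if (low_pct < 0 || high_pct > 100 || low_pct >= high_pct)
    stop("need 0 <= low_pct < high_pct <= 100")
  q <- quantile(stack$frames, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    out <- array(0.5, dim(stack$frames))
  } else {
    out <- pmin(pmax((stack$frames - q[1]) / (q[2] - q[1]), 0), 1)
  }
  thermal_stack(out, fps = stack$fps, pixel_scale = stack$pixel_scale,
                modality = stack$modality,
                origin_note = paste0(stack$origin_note, " | display-normalized"))
}
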