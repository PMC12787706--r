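#' Rectangular region of interest
#'
#' 1-based inclusive pixel rectangle, row 1 at the top of the frame.
#'
#' @param row0,col0 top-left corner.
#' @param row1,col1 bottom-right corner (`row1 >= row0`, `col1 >= col0`).
#' @return An object of class `RectROI`.
#' @export
rect_roi <- function(row0, col0, row1, col1) {
  if (row1 < row0 || col1 < col0)
    stop("RectROI corners must satisfy row1 >= row0 and col1 >= col0")
  if (row0 < 1 || col0 < 1) stop("RectROI must have positive coordinates")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 row1 = as.integer(row1), col1 = as.integer(col1)),
            class = "RectROI")
}

#' Extract the spatial-mean time series of a rectangular ROI
#'
#' The per-frame mean over the ROI (the z-axis profile of the region),
#' sampled at the stack frame rate.
#'
#' @param stack a [thermal_stack()].
#' @param roi a [rect_roi()] within the frame bounds.
#' @param label optional label for the returned signal.
#' @return A [time_series_signal()] with `fs = stack$fps`.
#' @export
extract_roi_signal <- function(stack, roi, label = "ROI mean") {
  stopifnot(inherits(stack, "ThermalStack"), inherits(roi, "RectROI"))
  d <- dim(stack$frames)
  if (roi$row1 > d[1] || roi$col1 > d[2])
    stop("ROI extends outside the frame (", d[1], " x ", d[2], ")")
  sub <- stack$frames[roi$row0:roi$row1, roi$col0:roi$col1, , drop = FALSE]
  vals <- colMeans(matrix(sub, prod(dim(sub)[1:2]), dim(sub)[3]))
  time_series_signal(vals, fs = stack$fps, label = label)
}

#' Average two bilateral signals
#'
#' Element-wise mean of the two nostril traces, as used for the reference
#' respiratory signal.
#'
#' @param a,b [time_series_signal()]s with identical `fs` and length.
#' @return A [time_series_signal()].
#' @export
average_bilateral <- function(a, b) {
  stopifnot(inherits(a, "TimeSeriesSignal"), inherits(b, "TimeSeriesSignal"))
  if (a$fs != b$fs) stop("signals have different sampling rates")
  if (length(a$values) != length(b$values))
    stop("signals have different lengths")
  time_series_signal((a$values + b$values) / 2, fs = a$fs,
                     label = "bilateral mean")
}

#' Negate a signal
#'
#' The visualized MWIR exhalation darkens during expiration; negating the
#' trace lets exhalation minima be counted as peaks with the same detector
#' used for exhale-positive (LWIR-like) signals.
#'
#' @param signal a [time_series_signal()].
#' @return The negated signal.
#' @export
invert <- function(signal) {
  stopifnot(inherits(signal, "TimeSeriesSignal"))
  time_series_signal(-signal$values, fs = signal$fs, label = signal$label)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Second-order (by default) Butterworth bandpass applied forward and
#' backward (`signal::filtfilt`), giving zero phase shift at the cost of a
#' doubled effective order. Rates, not phases, are reported downstream, and
#' forward-backward filtering is the standard way to avoid peak-time bias;
#' edge transients remain and the rate estimators exclude the first and
#' last seconds from peak counting.
#'
#' @param signal a [time_series_signal()].
#' @param f_lo,f_hi passband edges in Hz, `0 < f_lo < f_hi < fs/2`.
#' @param order filter order (2 matches a second-order Butterworth design).
#' @return A filtered [time_series_signal()] of the same length and `fs`.
#' @export
bandpass <- function(signal, f_lo, f_hi, order = 2L) {
  stopifnot(inherits(signal, "TimeSeriesSignal"))
  fs <- signal$fs
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < fs / 2))
    stop("passband must satisfy 0 < f_lo < f_hi < fs/2")
  n <- length(signal$values)
  min_n <- 3L * (2L * as.integer(order) + 1L)
  if (n < min_n)
    stop("signal too short for filter warm-up (need >= ", min_n, " samples)")
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  # remove the mean first: the passband excludes DC, and a large offset
  # otherwise excites a long edge transient in the forward-backward pass
  out <- signal::filtfilt(bf, signal$values - mean(signal$values))
  time_series_signal(out, fs = fs,
                     label = sprintf("%s [%g-%g Hz]", signal$label,
                                     f_lo, f_hi))
}

# Topographic prominence of candidate peak i: height above the higher of the
# two minima separating it from higher terrain (or the signal ends).
peak_prominence <- function(x, i) {
  n <- length(x)
  left <- if (i == 1L) x[1L] else {
    seg <- x[i:1L]
    higher <- which(seg > x[i])
    if (length(higher)) min(seg[1:(higher[1L])]) else min(seg)
  }
  right <- if (i == n) x[n] else {
    seg <- x[i:n]
    higher <- which(seg > x[i])
    if (length(higher)) min(seg[1:(higher[1L])]) else min(seg)
  }
  x[i] - max(left, right)
}

#' Detect local maxima with separation and prominence constraints
#'
#' Deterministic peak detector: candidate peaks are strict local maxima
#' (for a plateau of tied samples, the first index is taken); candidates
#' below the prominence floor are dropped; the minimum separation is then
#' enforced greedily in order of decreasing height (ties broken toward the
#' earlier peak). Adding a constant to the signal does not change the
#' result, and reversing the signal in time reverses the peak set.
#'
#' @param signal a [time_series_signal()].
#' @param min_separation_s minimum time between accepted peaks (s), > 0.
#' @param min_prominence minimum topographic prominence (signal units).
#' @return Strictly increasing integer peak indices (length >= 2).
#' @export
detect_peaks <- function(signal, min_separation_s, min_prominence = 0) {
  stopifnot(inherits(signal, "TimeSeriesSignal"))
  if (min_separation_s <= 0) stop("min_separation_s must be > 0")
  x <- signal$values
  n <- length(x)
  cand <- which(diff(c(-Inf, x)) > 0 & diff(c(x, -Inf)) <= 0)
  cand <- cand[cand > 1L & cand < n]
  if (length(cand) && min_prominence > 0) {
    prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
    cand <- cand[prom >= min_prominence]
  }
  if (length(cand) >= 2L) {
    min_sep <- min_separation_s * signal$fs
    ord <- cand[order(-x[cand], cand)]
    kept <- integer(0)
    for (i in ord)
      if (!length(kept) || all(abs(kept - i) >= min_sep))
        kept <- c(kept, i)
    cand <- sort(kept)
  }
  if (length(cand) < 2L)
    stop("fewer than 2 peaks found; cannot derive a rate")
  cand
}

#' Rate from mean peak-to-peak interval (time domain)
#'
#' All inter-peak intervals are averaged and the reciprocal of the mean
#' interval is multiplied by 60, giving the rate in breaths or beats per
#' minute.
#'
#' @param peaks strictly increasing peak indices (length >= 2).
#' @param fs sampling rate of the peak-bearing signal, Hz.
#' @return An object of class `RateEstimate` with fields `rate_bpm`,
#'   `method = "time_domain"`, `peak_indices`.
#' @export
rate_from_intervals <- function(peaks, fs) {
  if (length(peaks) < 2L) stop("need at least 2 peaks")
  if (any(diff(peaks) <= 0)) stop("peak indices must be strictly increasing")
  mean_int_s <- mean(diff(peaks)) / fs
  structure(list(rate_bpm = 60 / mean_int_s, method = "time_domain",
                 peak_indices = as.integer(peaks), band_hz = NULL),
            class = "RateEstimate")
}

#' Rate from the FFT spectral peak (frequency domain)
#'
#' The magnitude spectrum of the (mean-removed) signal is restricted to the
#' given band and the peak bin is taken; the rate is 60 times the peak
#' frequency. Raw FFT bins are used, with no zero padding or interpolation,
#' so the resolution is one bin, `1 / duration` Hz (0.025 Hz, i.e. 1.5 bpm,
#' for a 40-s record). Ties resolve to the lowest frequency.
#'
#' @param signal a [time_series_signal()] of duration at least `2 / band_hz[1]`.
#' @param band_hz numeric `(lo, hi)` search band in Hz.
#' @return An object of class `RateEstimate` with fields `rate_bpm`,
#'   `method = "frequency_domain"`, `peak_freq_hz`, `bin_width_hz`,
#'   `band_hz`.
#' @export
rate_from_spectrum <- function(signal, band_hz) {
  stopifnot(inherits(signal, "TimeSeriesSignal"), length(band_hz) == 2L)
  n <- length(signal$values)
  dur <- n / signal$fs
  if (dur < 2 / band_hz[1])
    stop("record too short: need duration >= 2 / band lower edge")
  mags <- Mod(fft(signal$values - mean(signal$values)))
  freqs <- (seq_len(n) - 1) * signal$fs / n
  keep <- freqs >= band_hz[1] & freqs <= band_hz[2] & freqs <= signal$fs / 2
  if (!any(keep)) stop("no FFT bins inside the requested band")
  scale_ref <- max(mags)
  in_band <- mags[keep]
  if (scale_ref <= 0 || max(in_band) <= 1e-12 * scale_ref)
    stop("no in-band spectral peak above zero")
  peak_f <- freqs[keep][which.max(in_band)]
  structure(list(rate_bpm = 60 * peak_f, method = "frequency_domain",
                 peak_freq_hz = peak_f, bin_width_hz = signal$fs / n,
                 band_hz = as.numeric(band_hz)),
            class = "RateEstimate")
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf("RateEstimate: %.2f bpm (%s)\n", x$rate_bpm, x$method))
  if (!is.null(x$band_hz))
    cat(sprintf("  band: %g-%g Hz\n", x$band_hz[1], x$band_hz[2]))
  if (!is.null(x$bin_width_hz))
    cat(sprintf("  FFT bin width: %g Hz (%.2f bpm)\n",
                x$bin_width_hz, 60 * x$bin_width_hz))
  invisible(x)
}

#' Bandpass-and-estimate rate wrapper
#'
#' The full rate path used for respiration, pulse and PPG reference
#' signals: bandpass the trace, then either count peak-to-peak intervals
#' (time domain, excluding an edge margin where forward-backward filtering
#' leaves transients) or take the FFT spectral peak over the band
#' (frequency domain, full record so the stated bin width applies).
#'
#' @param signal a raw [time_series_signal()].
#' @param band_hz numeric `(lo, hi)` passband in Hz (respiration 0.1-0.4;
#'   pulse 0.8-1.5).
#' @param method `"time_domain"` or `"frequency_domain"`.
#' @param edge_trim_s seconds dropped at each end before peak counting.
#' @param min_separation_s minimum peak separation; default `0.8 / band_hz[2]`.
#' @param min_prominence prominence floor; default 0.3 x the interquartile
#'   range of the filtered, trimmed signal (scale-free).
#' @param order Butterworth order, see [bandpass()].
#' @return A `RateEstimate`.
#' @export
estimate_rate <- function(signal, band_hz,
                          method = c("time_domain", "frequency_domain"),
                          edge_trim_s = 2, min_separation_s = NULL,
                          min_prominence = NULL, order = 2L) {
  method <- match.arg(method)
  filt <- bandpass(signal, band_hz[1], band_hz[2], order = order)
  if (method == "frequency_domain") return(rate_from_spectrum(filt, band_hz))
  trim <- floor(edge_trim_s * filt$fs)
  n <- length(filt$values)
  if (n - 2 * trim < 3L * (2L * order + 1L)) trim <- 0L
  core <- time_series_signal(filt$values[(trim + 1):(n - trim)],
                             fs = filt$fs, label = filt$label)
  if (is.null(min_separation_s)) min_separation_s <- 0.8 / band_hz[2]
  if (is.null(min_prominence))
    min_prominence <- 0.3 * diff(quantile(core$values, c(0.25, 0.75),
                                          names = FALSE))
  peaks <- detect_peaks(core, min_separation_s, min_prominence)
  est <- rate_from_intervals(peaks + trim, filt$fs)
  est$band_hz <- as.numeric(band_hz)
  est
}

#' Split a signal into consecutive cycles at anchor samples
#'
#' Consecutive anchor pairs delimit half-open cycles
#' `[anchor_k, anchor_{k+1})`; unequal cycle lengths are preserved.
#'
#' @param signal a [time_series_signal()].
#' @param anchors at least 3 strictly increasing sample indices.
#' @return A list of numeric vectors, one per cycle.
#' @export
segment_cycles <- function(signal, anchors) {
  stopifnot(inherits(signal, "TimeSeriesSignal"))
  anchors <- as.integer(anchors)
  if (length(anchors) < 3L) stop("need at least 3 anchors")
  if (any(diff(anchors) <= 0)) stop("anchors must be strictly increasing")
  if (anchors[1] < 1L || tail(anchors, 1L) > length(signal$values) + 1L)
    stop("anchors outside the signal")
  lapply(seq_len(length(anchors) - 1L), function(k)
    signal$values[anchors[k]:(anchors[k + 1L] - 1L)])
}

#' Average cycle template after temporal normalization
#'
#' Each cycle is linearly resampled to `n_points` and min-max scaled to
#' `[0, 1]`; the template is the per-point mean and SD across cycles.
#' Cycles with zero amplitude cannot be scaled and are excluded with a
#' warning.
#'
#' @param cycles list of numeric vectors (from [segment_cycles()]).
#' @param n_points resampled cycle length.
#' @return An object of class `CycleTemplate` with fields `n_points`,
#'   `mean_waveform`, `sd_waveform`, `n_cycles`.
#' @export
normalize_cycles <- function(cycles, n_points = 100L) {
  if (length(cycles) < 1L) stop("need at least one cycle")
  n_points <- as.integer(n_points)
  resampled <- list()
  for (cy in cycles) {
    rng <- range(cy)
    if (diff(rng) == 0) {
      warning("dropping zero-amplitude cycle")
      next
    }
    y <- approx(seq_along(cy), cy, n = n_points)$y
    resampled[[length(resampled) + 1L]] <- (y - min(y)) / (max(y) - min(y))
  }
  if (!length(resampled)) stop("all cycles had zero amplitude")
  m <- do.call(rbind, resampled)
  sds <- if (nrow(m) > 1L) apply(m, 2L, sd) else numeric(n_points)
  structure(list(n_points = n_points, mean_waveform = colMeans(m),
                 sd_waveform = sds, n_cycles = nrow(m)),
            class = "CycleTemplate")
}
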