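#' Thermal image stack
#'
#' Container for a thermal video: an H x W x T array of per-pixel values
#' (degrees Celsius for calibrated radiometric data, or arbitrary intensity),
#' the acquisition frame rate, an optional spatial calibration, and a modality
#' tag. Frames are stored spatial-major with time as the third array
#' dimension, so `frames[, , t]` is the t-th frame. All pixel coordinates in
#' this package are 1-based `(row, col)` with row 1 at the top of the image,
#' and rectangular regions are inclusive on both ends.
#'
#' @param frames numeric array with dimensions H x W x T (a single H x W
#'   matrix is promoted to T = 1). All values must be finite.
#' @param fps frames per second, > 0.
#' @param pixel_scale metres per pixel, > 0, or `NULL` when no spatial
#'   calibration is available. Required by the velocimetry functions.
#' @param modality one of `"MWIR"`, `"LWIR"`, `"SYNTHETIC"`.
#' @param origin_note free-text provenance note.
#'
#' @return An object of class `ThermalStack`.
#' @seealso [read_tiff_stack()], [write_tiff_stack()]
#' @export
thermal_stack <- function(frames, fps, pixel_scale = NULL,
                          modality = c("MWIR", "LWIR", "SYNTHETIC"),
                          origin_note = "") {
  modality <- match.arg(modality)
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array")
  if (any(dim(frames) < 1L)) stop("all stack dimensions must be >= 1")
  if (!all(is.finite(frames))) stop("stack contains non-finite values")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number")
  if (!is.null(pixel_scale)) {
    if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L ||
        pixel_scale <= 0)
      stop("`pixel_scale` must be a single positive number or NULL")
  }
  structure(
    list(frames = frames, fps = fps, pixel_scale = pixel_scale,
         modality = modality, origin_note = as.character(origin_note)[1L]),
    class = "ThermalStack")
}

#' @export
print.ThermalStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("ThermalStack: %d x %d px, %d frames @ %g fps [%s]\n",
              d[1], d[2], d[3], x$fps, x$modality))
  if (!is.null(x$pixel_scale))
    cat(sprintf("  pixel scale: %g m/px\n", x$pixel_scale))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(x$frames), max(x$frames)))
  if (nzchar(x$origin_note)) cat("  note:", x$origin_note, "\n")
  invisible(x)
}

#' @export
dim.ThermalStack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack a [thermal_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3L]

#' Uniformly sampled 1-D signal
#'
#' Carrier for region-of-interest traces, filtered signals and
#' photoplethysmography (PPG) recordings.
#'
#' @param values numeric vector, length >= 2, all finite.
#' @param fs sampling rate in samples per second, > 0.
#' @param label free-text label.
#' @return An object of class `TimeSeriesSignal`.
#' @export
time_series_signal <- function(values, fs, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("signal must have at least 2 samples")
  if (!all(is.finite(values))) stop("signal contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  structure(list(values = values, fs = fs, label = as.character(label)[1L]),
            class = "TimeSeriesSignal")
}

#' @export
print.TimeSeriesSignal <- function(x, ...) {
  cat(sprintf("TimeSeriesSignal%s: %d samples @ %g Hz (%.3g s)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' @export
length.TimeSeriesSignal <- function(x) length(x$values)

# Largest power of two <= x (x > 0); used for lossless float32 TIFF scaling.
pow2_floor <- function(x) 2^floor(log2(x))
pow2_ceil <- function(x) 2^ceiling(log2(x))

# TIFF samples must lie in [0, 1]; choose power-of-two gain/offset so that
# (x - offset) / gain is exact in binary floating point for data of
# homogeneous scale, making the round trip lossless for float32 input.
tiff_scaling <- function(lo, hi) {
  offset <- if (lo >= 0) 0 else -pow2_ceil(max(abs(lo), .Machine$double.xmin))
  span <- hi - offset
  gain <- if (span <= 0) 1 else pow2_ceil(span)
  list(gain = gain, offset = offset)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a thermal stack as a multi-page 32-bit TIFF with JSON sidecar
#'
#' Pages are stored as 32-bit samples, linearly mapped into `[0, 1]` with
#' a power-of-two gain and offset recorded in the sidecar (`<path>.json`)
#' together with `fps`, `pixel_scale_m_per_px` and `modality`. The
#' power-of-two mapping is exact in binary floating point; the only loss
#' is the 32-bit sample quantization, i.e. `gain * 2^-32` in stack units
#' (about 1.5e-8 degC for face-scale temperature data — far below any
#' sensor's resolution), which `read_tiff_stack()` inverts.
#'
#' @param stack a [thermal_stack()].
#' @param path output file path; the directory is created if absent.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ThermalStack"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  sc <- tiff_scaling(min(stack$frames), max(stack$frames))
  tcount <- n_frames(stack)
  pages <- lapply(seq_len(tcount), function(t)
    (stack$frames[, , t] - sc$offset) / sc$gain)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(fps = stack$fps,
               pixel_scale_m_per_px = stack$pixel_scale,
               modality = stack$modality,
               gain = sc$gain, offset = sc$offset,
               origin_note = stack$origin_note)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

read_tiff_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # 8/16-bit pages hold integer encodings which readTIFF normalizes into
  # [0, 1]; undo that so the sidecar gain/offset applies to raw counts.
  # 32-bit pages are float samples and arrive as stored.
  lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    if (!is.numeric(p)) stop("non-numeric pixels in ", path)
    p <- unclass(p)
    attributes(p) <- list(dim = dim(p))
    if (!is.null(bits) && bits < 32L) p <- round(p * (2^bits - 1))
    p
  })
}

#' Read a thermal stack from TIFF
#'
#' Accepts either a single multi-page TIFF or a directory of same-shaped
#' single-page TIFFs, taken in lexicographic filename order (zero-padded
#' frame indices are expected for frame-per-file recordings). Integer pixel
#' encodings are converted to physical values through the linear calibration
#' `value = raw * gain + offset`; `gain`/`offset` default to the identity and
#' are read from the JSON sidecar when one is present. Explicit arguments
#' override sidecar metadata.
#'
#' @param path a TIFF file or a directory of single-page TIFFs.
#' @param fps frames per second; required when no sidecar is present.
#' @param pixel_scale metres per pixel, optional.
#' @param modality `"MWIR"`, `"LWIR"` or `"SYNTHETIC"`; optional when a
#'   sidecar is present.
#' @param gain,offset linear calibration applied to the stored samples.
#' @return A [thermal_stack()].
#' @export
read_tiff_stack <- function(path, fps = NULL, pixel_scale = NULL,
                            modality = NULL, gain = NULL, offset = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  read_one <- function(f) {
    pages <- read_tiff_pages(f)
    sc <- sidecar_path(f)
    meta <- if (file.exists(sc)) jsonlite::read_json(sc) else list()
    # explicit arguments override the sidecar calibration
    g <- if (!is.null(gain)) gain else
      if (!is.null(meta$gain)) as.numeric(meta$gain) else 1
    o <- if (!is.null(offset)) offset else
      if (!is.null(meta$offset)) as.numeric(meta$offset) else 0
    list(pages = lapply(pages, function(p) p * g + o), meta = meta)
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF files in directory ", path)
    reads <- lapply(files, read_one)
    pages <- unlist(lapply(reads, `[[`, "pages"), recursive = FALSE)
    meta <- reads[[1L]]$meta
  } else {
    r <- read_one(path)
    pages <- r$pages
    meta <- r$meta
  }
  shp <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1L))))
    stop("inconsistent frame shapes in ", path)
  if (is.null(fps)) fps <- as.numeric(meta$fps)
  if (is.null(fps) || !length(fps))
    stop("`fps` not given and no sidecar metadata found")
  if (is.null(pixel_scale) && !is.null(meta$pixel_scale_m_per_px))
    pixel_scale <- as.numeric(meta$pixel_scale_m_per_px)
  if (is.null(modality))
    modality <- if (!is.null(meta$modality)) meta$modality else "MWIR"
  frames <- array(0, c(shp, length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]]
  note <- if (!is.null(meta$origin_note)) meta$origin_note else
    paste0("read from ", path)
  thermal_stack(frames, fps = fps, pixel_scale = pixel_scale,
                modality = modality, origin_note = note)
}

#' Read a one-column CSV signal
#'
#' Reads a plain-text export with one numeric value per line (an optional
#' non-numeric header line is skipped), as produced by thermal-camera
#' analysis software and pulse-oximeter loggers.
#'
#' @param path file path.
#' @param fs sampling rate of the stored signal in Hz.
#' @param label optional label for the returned signal.
#' @return A [time_series_signal()].
#' @export
read_signal_csv <- function(path, fs, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty signal file: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1L]) && length(lines) > 1L) {  # header line
    lines <- lines[-1L]
    vals <- suppressWarnings(as.numeric(lines))
  }
  if (anyNA(vals)) stop("non-numeric rows in ", path)
  time_series_signal(vals, fs = fs, label = label)
}

#' Write a signal as a one-column CSV
#'
#' @param signal a [time_series_signal()].
#' @param path output path.
#' @param header logical; write the signal label as a header line.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path, header = TRUE) {
  stopifnot(inherits(signal, "TimeSeriesSignal"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  lines <- format(signal$values, digits = 17, scientific = FALSE,
                  trim = TRUE)
  if (header) {
    lab <- if (nzchar(signal$label)) signal$label else "value"
    lines <- c(lab, lines)
  }
  writeLines(lines, path)
  invisible(path)
}
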