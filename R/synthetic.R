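#' Phantom recording configuration
#'
#' Parameters of the synthetic thermal-video phantom used to validate the
#' pipeline without instrument data. The defaults reproduce the acquisition
#' conditions the pipeline targets: 40-s spontaneous-breathing recordings at
#' 60 fps (MWIR) and 30 fps (LWIR) of a seated subject at ~24 degC ambient,
#' with a facial surface near 34 degC, inner-canthus hot spots at 36.5 degC
#' carrying a milli-kelvin cardiac oscillation, and per-pixel Gaussian noise
#' at the 18 mK temperature resolution typical of cooled InSb MWIR sensors.
#' The spatial grid is a scaled-down face (96 x 80 px at 2 mm/px) so that
#' full recordings stay small enough for routine testing.
#'
#' @param duration_s recording length in seconds. Must cover at least 4
#'   respiratory cycles.
#' @param fps MWIR frame rate (frames/s).
#' @param lwir_fps LWIR frame rate (frames/s).
#' @param height_px,width_px frame size in pixels.
#' @param pixel_scale_m_per_px spatial calibration (m/px).
#' @param ambient_C,face_temp_C,canthus_temp_C background, facial and
#'   inner-canthus temperatures (degC).
#' @param canthus_centres list of two `(row, col)` centres of the canthus
#'   spots (1-based).
#' @param canthus_radius_px radius of the canthus plateau discs.
#' @param pulse_amp_mK amplitude of the cardiac temperature oscillation at
#'   the canthi (milli-kelvin).
#' @param heart_rate_bpm,resp_rate_bpm ground-truth cardiac and respiratory
#'   rates (beats / breaths per minute); `resp_rate_bpm < heart_rate_bpm`.
#' @param nostril_centres list of two `(row, col)` nostril centres.
#' @param nostril_radius_px radius of the nostril discs (LWIR phantom).
#' @param nostril_area_m2 right and left nostril cross-sections (m^2),
#'   defaults 7.18e-5 and 5.85e-5.
#' @param plume_velocity_m_per_s advection speed of the exhaled plume (m/s).
#' @param plume_absorption_depth_C intensity decrement of the exhaled CO2
#'   plume (image units ~ degC).
#' @param plume_sigma_px Gaussian cross-section of the plume (px).
#' @param plume_texture_wavelength_px wavelength of the advected texture
#'   riding on the plume; `NULL` selects `max(12, 3 * displacement/frame)`
#'   so that frame-rate sampling never aliases the motion.
#' @param lwir_nostril_amp_C amplitude of the exhalation temperature rise at
#'   the nostrils in the LWIR phantom (degC).
#' @param exhale_duty fraction of each respiratory cycle spent exhaling
#'   (exhalation occupies the first part of each cycle).
#' @param noise_sd_mK per-pixel white-noise SD (milli-kelvin).
#' @param seed integer seed fixing all randomness.
#' @return An object of class `PhantomConfig` (a validated list).
#' @export
phantom_config <- function(duration_s = 40, fps = 60, lwir_fps = 30,
                           height_px = 96, width_px = 80,
                           pixel_scale_m_per_px = 2e-3,
                           ambient_C = 24, face_temp_C = 34,
                           canthus_temp_C = 36.5,
                           canthus_centres = list(c(28, 30), c(28, 50)),
                           canthus_radius_px = 2.5,
                           pulse_amp_mK = 30,
                           heart_rate_bpm = 72, resp_rate_bpm = 15,
                           nostril_centres = list(c(50, 32), c(50, 48)),
                           nostril_radius_px = 2.5,
                           nostril_area_m2 = c(7.18e-5, 5.85e-5),
                           plume_velocity_m_per_s = 1.0,
                           plume_absorption_depth_C = 0.5,
                           plume_sigma_px = 2.5,
                           plume_texture_wavelength_px = NULL,
                           lwir_nostril_amp_C = 1.0,
                           exhale_duty = 0.5,
                           noise_sd_mK = 18,
                           seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$resp_rate_bpm <= 0 || cfg$heart_rate_bpm <= cfg$resp_rate_bpm)
    stop("need 0 < resp_rate_bpm < heart_rate_bpm")
  if (cfg$duration_s * cfg$resp_rate_bpm / 60 < 4)
    stop("recording must cover at least 4 respiratory cycles")
  if (cfg$duration_s <= 0 || cfg$fps <= 0 || cfg$lwir_fps <= 0)
    stop("duration and frame rates must be positive")
  amps <- c(cfg$pulse_amp_mK, cfg$plume_absorption_depth_C,
            cfg$lwir_nostril_amp_C, cfg$noise_sd_mK)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  if (cfg$exhale_duty <= 0 || cfg$exhale_duty >= 1)
    stop("exhale_duty must be in (0, 1)")
  if (length(cfg$canthus_centres) != 2L || length(cfg$nostril_centres) != 2L)
    stop("exactly two canthus and two nostril centres are required")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "PhantomConfig")
}

#' Ground-truth exhalation windows of a phantom configuration
#'
#' Exhalation occupies the first `exhale_duty` fraction of each respiratory
#' cycle; windows tile the recording at exactly the configured rate.
#'
#' @param config a [phantom_config()].
#' @return A two-column matrix of `(t_start, t_end)` in seconds.
#' @export
exhalation_windows <- function(config) {
  tc <- 60 / config$resp_rate_bpm
  n <- floor(config$duration_s / tc + 1e-9)
  k <- seq_len(n) - 1
  cbind(t_start = k * tc, t_end = k * tc + config$exhale_duty * tc)
}

ground_truth <- function(config) {
  structure(list(
    resp_rate_bpm = config$resp_rate_bpm,
    heart_rate_bpm = config$heart_rate_bpm,
    body_temp_C = config$canthus_temp_C,
    plume_velocity_m_per_s = config$plume_velocity_m_per_s,
    exhalation_windows = exhalation_windows(config)
  ), class = "GroundTruth")
}

disc_mask <- function(h, w, centre, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - centre[1])^2 + (cc - centre[2])^2 <= radius^2
}

ellipse_mask <- function(h, w, centre, semi) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rr - centre[1]) / semi[1])^2 + ((cc - centre[2]) / semi[2])^2 <= 1
}

face_geometry <- function(config) {
  h <- config$height_px; w <- config$width_px
  list(centre = c(round(0.45 * h), round(w / 2)),
       semi = c(round(0.42 * h), round(0.40 * w)))
}

phantom_base_image <- function(config) {
  h <- config$height_px; w <- config$width_px
  geo <- face_geometry(config)
  img <- matrix(config$ambient_C, h, w)
  img[ellipse_mask(h, w, geo$centre, geo$semi)] <- config$face_temp_C
  for (ct in config$canthus_centres)
    img[disc_mask(h, w, ct, config$canthus_radius_px)] <- config$canthus_temp_C
  img
}

plume_texture <- function(d_px, front_px, wavelength_px, depth) {
  on <- as.numeric(d_px <= front_px)
  depth * on * (0.7 + 0.3 * cos(2 * pi * (d_px - front_px) / wavelength_px))
}

plume_wavelength <- function(config) {
  slope <- config$plume_velocity_m_per_s /
    (config$pixel_scale_m_per_px * config$fps)
  wl <- config$plume_texture_wavelength_px
  if (is.null(wl)) wl <- max(12, 3 * slope)
  wl
}

# Geometry of one nostril plume: axis rows, distances, columns and weights.
plume_geometry <- function(config, nostril) {
  h <- config$height_px; w <- config$width_px
  r0 <- nostril[1] + ceiling(config$nostril_radius_px) + 1
  if (h - r0 < 8)
    stop("phantom config error: plume axis leaves the frame after <8 px; ",
         "move the nostrils up or enlarge the frame")
  rows <- r0:h
  span <- ceiling(3 * config$plume_sigma_px)
  cols <- max(1, nostril[2] - span):min(w, nostril[2] + span)
  list(rows = rows, d = rows - r0,
       cols = cols,
       wcol = exp(-((cols - nostril[2])^2) / (2 * config$plume_sigma_px^2)))
}

#' Generate the MWIR phantom recording
#'
#' Produces a seeded synthetic MWIR stack: a warm elliptical face over an
#' ambient background; two inner-canthus plateaus carrying a sinusoidal
#' cardiac oscillation; and, during the expiratory part of each respiratory
#' cycle, a dark plume below each nostril emulating CO2 absorption. The
#' plume is an advected intensity decrement along a fixed downward axis: its
#' front advances at the configured velocity and a sinusoidal texture rides
#' on it at the same speed, so a space-time image taken along the axis shows
#' streaks of slope `velocity / (pixel_scale * fps)` px/frame. White
#' Gaussian noise is added per pixel per frame.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `stack` (a [thermal_stack()], modality
#'   `"SYNTHETIC"`) and `truth` (ground-truth rates, temperature, plume
#'   velocity and exhalation windows).
#' @export
generate_mwir_phantom <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  h <- config$height_px; w <- config$width_px
  nt <- round(config$duration_s * config$fps)
  tsec <- (seq_len(nt) - 1) / config$fps
  base <- phantom_base_image(config)
  frames <- array(base, c(h, w, nt))

  # cardiac oscillation on the canthus plateaus
  amp_c <- config$pulse_amp_mK / 1000
  if (amp_c > 0) {
    cmask <- Reduce(`|`, lapply(config$canthus_centres, function(ct)
      disc_mask(h, w, ct, config$canthus_radius_px)))
    idx <- which(cmask)
    pulse <- amp_c * sin(2 * pi * (config$heart_rate_bpm / 60) * tsec)
    frames[outer(idx, (seq_len(nt) - 1) * h * w, `+`)] <-
      frames[outer(idx, (seq_len(nt) - 1) * h * w, `+`)] +
      rep(pulse, each = length(idx))
  }

  # exhaled plumes
  depth <- config$plume_absorption_depth_C
  if (depth > 0) {
    wl <- plume_wavelength(config)
    v_px_s <- config$plume_velocity_m_per_s / config$pixel_scale_m_per_px
    geos <- lapply(config$nostril_centres, function(ns)
      plume_geometry(config, ns))
    win <- exhalation_windows(config)
    for (k in seq_len(nrow(win))) {
      tt <- which(tsec >= win[k, 1] & tsec < win[k, 2])
      for (t in tt) {
        front <- v_px_s * (tsec[t] - win[k, 1])
        for (g in geos) {
          dec <- plume_texture(g$d, front, wl, depth)
          frames[g$rows, g$cols, t] <- frames[g$rows, g$cols, t] -
            outer(dec, g$wcol)
        }
      }
    }
  }

  noise_c <- config$noise_sd_mK / 1000
  frames <- withr::with_seed(config$seed, {
    if (noise_c > 0) frames + rnorm(length(frames), 0, noise_c) else frames
  })
  list(stack = thermal_stack(frames, fps = config$fps,
                             pixel_scale = config$pixel_scale_m_per_px,
                             modality = "SYNTHETIC",
                             origin_note = "MWIR phantom"),
       truth = ground_truth(config))
}

# Capnogram-like cycle shape on [0, 1): fast rise, plateau, fast fall,
# baseline. Amplitude 1 at the plateau.
capnogram_phase <- function(phase, duty) {
  ramp <- min(0.08, duty / 3)
  y <- numeric(length(phase))
  up <- phase < ramp
  y[up] <- phase[up] / ramp
  plateau <- phase >= ramp & phase < duty
  y[plateau] <- 1
  down <- phase >= duty & phase < duty + ramp
  y[down] <- 1 - (phase[down] - duty) / ramp
  y
}

#' Generate the LWIR phantom recording
#'
#' Emulates the long-wave reference camera: the nostril regions warm with
#' exhalation and cool with inhalation, following a capnogram-like waveform
#' (fast upstroke, plateau, fast downstroke, baseline) at the configured
#' respiratory rate, in phase opposition to the MWIR plume signal. No plume
#' is drawn. Runs at `config$lwir_fps`.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `stack` and `truth`, as
#'   [generate_mwir_phantom()].
#' @export
generate_lwir_phantom <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  h <- config$height_px; w <- config$width_px
  nt <- round(config$duration_s * config$lwir_fps)
  tsec <- (seq_len(nt) - 1) / config$lwir_fps
  geo <- face_geometry(config)
  base <- matrix(config$ambient_C, h, w)
  base[ellipse_mask(h, w, geo$centre, geo$semi)] <- config$face_temp_C
  nmask <- Reduce(`|`, lapply(config$nostril_centres, function(ns)
    disc_mask(h, w, ns, config$nostril_radius_px)))
  base[nmask] <- config$face_temp_C - 1  # resting nostril baseline
  frames <- array(base, c(h, w, nt))

  tc <- 60 / config$resp_rate_bpm
  phase <- (tsec %% tc) / tc
  wave <- config$lwir_nostril_amp_C * capnogram_phase(phase, config$exhale_duty)
  idx <- which(nmask)
  frames[outer(idx, (seq_len(nt) - 1) * h * w, `+`)] <-
    frames[outer(idx, (seq_len(nt) - 1) * h * w, `+`)] +
    rep(wave, each = length(idx))

  noise_c <- config$noise_sd_mK / 1000
  frames <- withr::with_seed(config$seed + 1L, {
    if (noise_c > 0) frames + rnorm(length(frames), 0, noise_c) else frames
  })
  list(stack = thermal_stack(frames, fps = config$lwir_fps,
                             pixel_scale = config$pixel_scale_m_per_px,
                             modality = "SYNTHETIC",
                             origin_note = "LWIR phantom"),
       truth = ground_truth(config))
}

#' Generate a synthetic photoplethysmography trace
#'
#' A unit-amplitude cardiac sinusoid at `heart_rate_bpm / 60` Hz plus a
#' respiratory baseline modulation at `resp_rate_bpm / 60` Hz and white
#' noise, sampled at the pulse-oximeter rate.
#'
#' @param config a [phantom_config()].
#' @param fs sampling rate in Hz (pulse-oximeter default 409.6).
#' @param resp_amp,noise_sd amplitudes of the respiratory modulation and the
#'   additive noise, relative to the unit cardiac component.
#' @return A [time_series_signal()].
#' @export
generate_ppg <- function(config, fs = 409.6, resp_amp = 0.3,
                         noise_sd = 0.05) {
  stopifnot(inherits(config, "PhantomConfig"))
  n <- round(config$duration_s * fs)
  tsec <- (seq_len(n) - 1) / fs
  vals <- sin(2 * pi * (config$heart_rate_bpm / 60) * tsec) +
    resp_amp * sin(2 * pi * (config$resp_rate_bpm / 60) * tsec)
  vals <- withr::with_seed(config$seed + 2L, {
    if (noise_sd > 0) vals + rnorm(n, 0, noise_sd) else vals
  })
  time_series_signal(vals, fs = fs, label = "synthetic PPG")
}

#' Generate a standalone synthetic space-time image
#'
#' Parallel dark streaks advancing `slope_px_per_frame` pixels along the
#' space axis per time step, for exercising the orientation estimator in
#' isolation. The ground-truth streak angle, measured from the space axis,
#' is `atan(1 / slope)` (45 degrees at slope 1; approaching 0 as the slope
#' grows and streaks become near-horizontal).
#'
#' @param slope_px_per_frame streak advance per frame (> 0).
#' @param n_time,n_space image size (time rows x space columns).
#' @param streak_spacing_px wavelength of the streak pattern.
#' @param noise_sd additive white-noise SD (image units; contrast is 0.5).
#' @param seed integer seed.
#' @param sx,st unit scales (m/px along space, s/px along time).
#' @return A list with elements `sti` (a [space_time_image()]) and
#'   `theta_deg` (the ground-truth angle).
#' @export
generate_sti <- function(slope_px_per_frame, n_time = 120, n_space = 64,
                         streak_spacing_px = 10, noise_sd = 0, seed = 1L,
                         sx = 1, st = 1) {
  if (slope_px_per_frame <= 0) stop("slope must be > 0")
  x <- matrix(seq_len(n_space) - 1, n_time, n_space, byrow = TRUE)
  t <- matrix(seq_len(n_time) - 1, n_time, n_space)
  vals <- 1 - 0.5 * (0.5 + 0.5 *
    cos(2 * pi * (x - slope_px_per_frame * t) / streak_spacing_px))
  vals <- withr::with_seed(as.integer(seed), {
    if (noise_sd > 0) vals + rnorm(length(vals), 0, noise_sd) else vals
  })
  list(sti = space_time_image(vals, sx = sx, st = st,
                              provenance = "synthetic streak pattern"),
       theta_deg = atan(1 / slope_px_per_frame) * 180 / pi)
}

#' Default regions of interest for a phantom configuration
#'
#' Convenience accessor mirroring how an operator would place regions on a
#' real recording: a rectangle over the visualized exhalation just below the
#' nostrils (MWIR respiratory signal), one rectangle per nostril (LWIR
#' reference signal), and one vertical line per nostril along the plume axis
#' (velocimetry).
#'
#' @param config a [phantom_config()].
#' @return A list with elements `plume` ([rect_roi()]), `nostrils` (list of
#'   two [rect_roi()]s) and `lines` (list of two [line_roi()]s).
#' @export
phantom_rois <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  ns <- config$nostril_centres
  r0 <- ns[[1]][1] + ceiling(config$nostril_radius_px) + 1
  cols <- range(vapply(ns, `[`, numeric(1), 2))
  span <- ceiling(config$plume_sigma_px)
  plume <- rect_roi(r0 + 1, cols[1] - span, r0 + 10, cols[2] + span)
  nostrils <- lapply(ns, function(x) {
    r <- ceiling(config$nostril_radius_px)
    rect_roi(x[1] - r, x[2] - r, x[1] + r, x[2] + r)
  })
  lines <- lapply(ns, function(x)
    line_roi(r0, x[2], config$height_px, x[2]))
  list(plume = plume, nostrils = nostrils, lines = lines)
}
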