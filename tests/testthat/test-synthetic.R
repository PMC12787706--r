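test_that("phantom configurations are validated", {
  expect_error(phantom_config(resp_rate_bpm = 80, heart_rate_bpm = 70),
               "resp_rate_bpm < heart_rate_bpm")
  expect_error(phantom_config(duration_s = 10, resp_rate_bpm = 12),
               "4 respiratory cycles")
  expect_error(phantom_config(exhale_duty = 1.2), "exhale_duty")
  expect_error(phantom_config(noise_sd_mK = -1), "amplitudes")
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- quick_config(seed = 7)
  a <- generate_mwir_phantom(cfg)
  b <- generate_mwir_phantom(cfg)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(generate_ppg(cfg)$values, generate_ppg(cfg)$values)
  expect_identical(generate_lwir_phantom(cfg)$stack$frames,
                   generate_lwir_phantom(cfg)$stack$frames)
})

test_that("zeroed modulations give a static scene", {
  cfg <- quick_config(pulse_amp_mK = 0, plume_absorption_depth_C = 0,
                      noise_sd_mK = 0)
  mw <- generate_mwir_phantom(cfg)
  expect_true(all(mw$stack$frames ==
                    array(mw$stack$frames[, , 1], dim(mw$stack$frames))))
  ms <- mean_subtract(mw$stack)
  expect_true(all(ms$frames == 0))
})

test_that("exhalation windows tile the recording at the configured rate", {
  cfg <- phantom_config(duration_s = 40, resp_rate_bpm = 15)
  win <- exhalation_windows(cfg)
  expect_equal(nrow(win), 10)  # 15 bpm over 40/60 min
  expect_equal(win[, 1], (0:9) * 4)
  expect_equal(win[, 2] - win[, 1], rep(2, 10))  # duty cycle 0.5
  gt <- generate_mwir_phantom(cfg)$truth
  expect_equal(gt$exhalation_windows, win)
})

test_that("the plume front advances at velocity / (scale * fps) px per frame", {
  cfg <- quick_config(noise_sd_mK = 0, pulse_amp_mK = 0,
                      plume_velocity_m_per_s = 1.0)
  v_px <- 1.0 / (cfg$pixel_scale_m_per_px * cfg$fps)
  expect_equal(v_px, 8.3333, tolerance = 1e-4)
  mw <- generate_mwir_phantom(cfg)
  base <- generate_mwir_phantom(quick_config(noise_sd_mK = 0,
                                             pulse_amp_mK = 0,
                                             plume_absorption_depth_C = 0))
  dec <- base$stack$frames - mw$stack$frames  # decrement field, >= 0
  nostril <- cfg$nostril_centres[[1]]
  col <- nostril[2]
  r0 <- nostril[1] + ceiling(cfg$nostril_radius_px) + 1
  # frame k (0-based time k/fps into the first exhalation): front at v_px*k
  for (k in c(1, 2, 3)) {
    d <- dec[r0:cfg$height_px, col, k + 1]
    reached <- which(d > 1e-9)
    expect_true(length(reached) > 0)
    expect_lte(max(reached) - 1, v_px * k + 1e-9)
    expect_gte(max(reached) - 1, v_px * k - 1.5)
  }
})

test_that("LWIR nostril signal is capnogram-like and anti-phased to MWIR", {
  cfg <- quick_config(noise_sd_mK = 0, pulse_amp_mK = 0)
  lw <- generate_lwir_phantom(cfg)
  ns <- cfg$nostril_centres[[1]]
  px <- lw$stack$frames[ns[1], ns[2], ]
  # zero-noise waveform spans baseline .. baseline + amplitude
  expect_equal(min(px), cfg$face_temp_C - 1)
  expect_equal(max(px), cfg$face_temp_C - 1 + cfg$lwir_nostril_amp_C)
  # fundamental at the respiratory frequency
  mags <- Mod(fft(px - mean(px)))
  n <- length(px)
  freqs <- (seq_len(n) - 1) * cfg$lwir_fps / n
  half <- freqs > 0 & freqs <= cfg$lwir_fps / 2
  f_peak <- freqs[half][which.max(mags[half])]
  expect_equal(f_peak, cfg$resp_rate_bpm / 60, tolerance = 1e-6)

  # MWIR exhalation trace is inverse phased: darkens while LWIR warms
  mw <- generate_mwir_phantom(cfg)
  rois <- phantom_rois(cfg)
  mw_sig <- extract_roi_signal(mw$stack, rois$plume)$values
  lw_sig <- extract_roi_signal(lw$stack, rois$nostrils[[1]])$values
  mw_30 <- mw_sig[seq(1, length(mw_sig), by = 2)]  # 60 -> 30 fps
  expect_lt(cor(mw_30, lw_sig), -0.5)
})

test_that("PPG has the cardiac fundamental and the configured length", {
  cfg <- quick_config()
  ppg <- generate_ppg(cfg)
  expect_equal(length(ppg$values), round(cfg$duration_s * 409.6))
  n <- length(ppg$values)
  mags <- Mod(fft(ppg$values - mean(ppg$values)))
  freqs <- (seq_len(n) - 1) * ppg$fs / n
  card <- freqs >= 0.8 & freqs <= 2
  f_peak <- freqs[card][which.max(mags[card])]
  expect_lt(abs(f_peak - cfg$heart_rate_bpm / 60), ppg$fs / n + 1e-9)
})

test_that("synthetic STIs encode the requested streak slope", {
  g <- generate_sti(1, n_time = 60, n_space = 40)
  expect_equal(g$theta_deg, 45)
  expect_equal(dim(g$sti$values), c(60, 40))
  g2 <- generate_sti(10)
  expect_lt(g2$theta_deg, 6)  # near-horizontal streaks as slope grows
  expect_error(generate_sti(0), "slope")
  expect_identical(generate_sti(2, noise_sd = 0.1, seed = 3)$sti$values,
                   generate_sti(2, noise_sd = 0.1, seed = 3)$sti$values)
})

test_that("a plume axis that leaves the frame is a config error", {
  cfg <- quick_config()
  cfg$nostril_centres <- list(c(92, 32), c(92, 48))
  expect_error(generate_mwir_phantom(cfg), "plume axis")
})
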