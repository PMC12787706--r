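test_that("temporal mean image averages frames pixel-wise", {
  a <- matrix(1:6, 2, 3); b <- matrix(7:12, 2, 3)
  st <- thermal_stack(array(c(a, b), c(2, 3, 2)), fps = 30,
                      modality = "MWIR")
  expect_equal(temporal_mean_image(st), (a + b) / 2)
  # cross-check with breath_viz: mean of a mean-subtracted stack is zero
  mw <- generate_mwir_phantom(quick_config())
  expect_lt(max(abs(temporal_mean_image(mean_subtract(mw$stack)))), 1e-9)
})

test_that("threshold segmentation keeps the two hottest plateaus", {
  img <- matrix(34, 20, 30)
  img[3:5, 4:6] <- 36.5
  img[3:5, 20:22] <- 36.5
  m <- segment_hottest(img, threshold_c = 36)
  expect_equal(m$component_count, 2)
  expect_equal(sum(m$mask), 18)
  expect_true(all(m$mask[3:5, 4:6]))
  expect_true(all(m$mask[3:5, 20:22]))
  expect_error(segment_hottest(img, threshold_c = 40), "exceeds")
  # threshold at the minimum: whole frame is one candidate component
  all_in <- segment_hottest(img, threshold_c = 34)
  expect_equal(sum(all_in$mask), length(img))
})

test_that("component labeling is 8-connected and area-filtered", {
  img <- matrix(0, 10, 10)
  img[2, 2] <- 1; img[3, 3] <- 1; img[4, 4] <- 1; img[5, 5] <- 1
  # a diagonal chain is a single 8-connected component
  m <- segment_hottest(img, threshold_c = 0.5, keep_components = 2,
                       min_area_px = 4)
  expect_equal(m$component_count, 1)
  expect_equal(sum(m$mask), 4)
  # but it is below min_area_px = 5
  expect_error(segment_hottest(img, threshold_c = 0.5, min_area_px = 5),
               "min_area_px")
})

test_that("percentile thresholds are invariant to constant shifts", {
  mw <- generate_mwir_phantom(quick_config())
  img <- temporal_mean_image(mw$stack)
  m1 <- segment_hottest(img, threshold_pct = 99.5)
  m2 <- segment_hottest(img + 5, threshold_pct = 99.5)
  expect_identical(m1$mask, m2$mask)
})

test_that("body temperature recovers the canthus plateau", {
  img <- matrix(34, 8, 8); img[2:4, 2:4] <- 36.5
  st <- thermal_stack(array(img, c(8, 8, 10)), fps = 60, modality = "MWIR")
  m <- segment_hottest(img, threshold_c = 36)
  expect_equal(body_temperature(st, m), 36.5)

  # a +/-30 mK cardiac sinusoid averages out over whole cycles
  cfg <- quick_config(noise_sd_mK = 0, plume_absorption_depth_C = 0)
  mw <- generate_mwir_phantom(cfg)
  mask <- segment_hottest(temporal_mean_image(mw$stack), threshold_c = 36)
  expect_lt(abs(body_temperature(mw$stack, mask) - 36.5), 1e-3)
})

test_that("canthus signal feeds the pulse path at the configured rate", {
  cfg <- quick_config(pulse_amp_mK = 54)
  mw <- generate_mwir_phantom(cfg)
  mask <- segment_hottest(temporal_mean_image(mw$stack), threshold_c = 36)
  sig <- canthus_signal(mw$stack, mask)
  expect_equal(sig$fs, cfg$fps)
  est <- estimate_rate(sig, c(0.8, 1.5), "time_domain")
  expect_lt(abs(est$rate_bpm - cfg$heart_rate_bpm), 2)
  # filtered amplitude tracks the configured pulse amplitude
  filt <- bandpass(sig, 0.8, 1.5)
  core <- filt$values[(2 * cfg$fps):(length(filt$values) - 2 * cfg$fps)]
  amp <- (quantile(core, 0.99, names = FALSE) -
            quantile(core, 0.01, names = FALSE)) / 2
  expect_lt(abs(amp - 0.054) / 0.054, 0.20)
})

test_that("masked operations fail cleanly on shape mismatch", {
  mw <- generate_mwir_phantom(quick_config())
  m <- segment_hottest(matrix(c(1, 2, 3, 4), 2, 2), threshold_c = 3,
                       min_area_px = 1)
  expect_error(body_temperature(mw$stack, m), "shape")
})
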