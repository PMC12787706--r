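test_that("reslice samples the line bilinearly at unit spacing", {
  # linear field: bilinear interpolation is exact
  frame <- outer(1:20, 1:30, function(r, c) 2 * r + 3 * c)
  st <- thermal_stack(array(frame, c(20, 30, 4)), fps = 60,
                      pixel_scale = 2e-3, modality = "MWIR")
  line <- line_roi(5, 3, 5, 27)  # horizontal, length 24
  sti <- reslice(st, line)
  expect_equal(dim(sti$values), c(4, 25))  # floor(L) + 1 samples
  expect_equal(sti$values[1, ], 2 * 5 + 3 * (3:27))
  expect_equal(sti$sx, 2e-3)
  expect_equal(sti$st, 1 / 60)

  diag <- reslice(st, line_roi(2.5, 2.5, 12.5, 22.5))
  len <- sqrt(10^2 + 20^2)
  s <- (seq_len(ncol(diag$values)) - 1) / len  # 1-px spacing along the line
  expect_equal(diag$values[2, ],
               2 * (2.5 + 10 * s) + 3 * (2.5 + 20 * s), tolerance = 1e-9)

  st$pixel_scale <- NULL
  expect_error(reslice(st, line), "pixel_scale")
  expect_equal(reslice(st, line, allow_pixel_units = TRUE)$sx, 1)
  expect_error(line_roi(1, 1, 1, 1), "nonzero length")
})

test_that("median filtering removes impulses and preserves constants", {
  v <- matrix(0.5, 6, 31)
  sti <- space_time_image(v, sx = 1, st = 1)
  expect_equal(denoise_sti(sti, 15)$values, v)
  v2 <- v; v2[3, 16] <- 9
  out <- denoise_sti(space_time_image(v2, 1, 1), 15)
  expect_equal(out$values, v)
  expect_error(denoise_sti(sti, 4), "odd")
  expect_error(denoise_sti(sti, 33), "larger than")
})

test_that("contrast enhancement bounds output and warns on constants", {
  g <- generate_sti(1, n_time = 64, n_space = 48, noise_sd = 0.02, seed = 2)
  eq <- enhance_contrast(g$sti)
  expect_gte(min(eq$values), 0)
  expect_lte(max(eq$values), 1)
  expect_equal(dim(eq$values), dim(g$sti$values))
  const <- space_time_image(matrix(2, 20, 20), 1, 1)
  expect_warning(out <- enhance_contrast(const), "constant")
  expect_equal(out$values, const$values)
})

test_that("exhalation cropping returns one sub-STI per window", {
  sti <- space_time_image(matrix(rnorm(600), 60, 10), sx = 1, st = 0.1)
  win <- cbind(c(0, 2, 4), c(1.5, 3.5, 5.5))
  crops <- crop_exhalation(sti, win)
  expect_length(crops, 3)
  expect_equal(nrow(crops[[1]]$values), 15)
  expect_equal(ncol(crops[[2]]$values), 10)
  expect_error(crop_exhalation(sti, cbind(1, 1)), "empty")
  expect_error(crop_exhalation(sti, cbind(10, 11)), "outside")
})

test_that("mean orientation recovers synthetic streak angles within 1 degree", {
  for (slope in c(1, 2)) {
    g <- generate_sti(slope, n_time = 120, n_space = 64)
    th <- mean_orientation(g$sti)
    expect_lt(abs(th - g$theta_deg), 1)
  }
  expect_error(mean_orientation(space_time_image(matrix(1, 30, 30), 1, 1)),
               "gradient energy")
  expect_error(mean_orientation(space_time_image(matrix(1:28, 4, 7), 1, 1)),
               "8 x 8")
})

test_that("mean orientation is invariant to affine rescaling and mild noise", {
  g <- generate_sti(1.5, n_time = 120, n_space = 64)
  th0 <- mean_orientation(g$sti)
  resc <- space_time_image(3.7 * g$sti$values - 12, 1, 1)
  expect_equal(mean_orientation(resc), th0, tolerance = 1e-9)
  gn <- generate_sti(1.5, n_time = 120, n_space = 64, noise_sd = 0.05,
                     seed = 11)  # 10% of the 0.5 streak contrast
  expect_lt(abs(mean_orientation(gn$sti) - th0), 2)
})

test_that("gradient-tensor orientation matches the rotated-line oracle", {
  for (slope in c(0.75, 1, 2, 3)) {
    # keep the streak texture well sampled in time as the slope grows
    g <- generate_sti(slope, n_time = 96, n_space = 72,
                      streak_spacing_px = max(12, 8 * slope))
    est <- mean_orientation(g$sti, n_bins = 360)
    orc <- oracle_orientation(g$sti)
    expect_lt(abs(est - orc), 1)
  }
})

test_that("velocity follows the streak-angle geometry, monotone in theta", {
  expect_equal(velocity_from_theta(45, 1, 1), 1)
  expect_equal(velocity_from_theta(45, 2e-3, 1 / 60), 0.12)
  th <- seq(5, 85, by = 5)
  u <- velocity_from_theta(th, 1, 1)
  expect_true(all(diff(u) < 0))
  expect_lt(velocity_from_theta(89.9, 1, 1), 0.002)  # stationary limit
  expect_error(velocity_from_theta(0, 1, 1), "strictly inside")
  expect_error(velocity_from_theta(90, 1, 1), "strictly inside")
})

test_that("flow and CO2 volume identities hold exactly", {
  expect_equal(flow_volume(1, 7.18e-5), 7.18e-5)
  expect_equal(flow_volume(0, 7.18e-5), 0)
  expect_identical(flow_volume(2, 5.85e-5), 2 * flow_volume(1, 5.85e-5))
  expect_error(flow_volume(-1, 1), ">= 0")
  expect_error(flow_volume(1, 0), "> 0")
  expect_equal(co2_volume(1, 0.04), 0.04)
  expect_equal(co2_volume(0), 0)
  expect_error(co2_volume(1, 1.5), "fraction")
  expect_equal(per_hour(0), 0)
  expect_equal(per_hour(1 / 3600), 1)

  fe <- flow_estimate(1.234, 7.18e-5, theta_deg = 6.9)
  expect_identical(fe$V, fe$U * fe$area_m2)
  expect_identical(fe$V_CO2, fe$co2_fraction * fe$V)
})

test_that("sinc time-resampling preserves well-sampled streak geometry", {
  g <- generate_sti(2, n_time = 80, n_space = 48, streak_spacing_px = 12)
  up <- mwirvitals:::sti_resample_time(g$sti, 4L)
  expect_equal(nrow(up$values), 4 * 79 + 1)
  expect_equal(up$st, g$sti$st / 4)
  th_up <- mean_orientation(up, n_bins = 360)
  # slope per resampled row is 0.5 -> 63.4 degrees from the space axis
  expect_lt(abs(th_up - atan(4 / 2) * 180 / pi), 1.5)
})

test_that("end-to-end STIV recovers the phantom plume velocity", {
  cfg <- quick_config(plume_velocity_m_per_s = 1.0)
  mw <- generate_mwir_phantom(cfg)
  sv <- stiv_velocity(mw$stack, phantom_rois(cfg)$lines[[1]],
                      mw$truth$exhalation_windows, median_window = 5)
  expect_lt(abs(sv$u_mean - 1.0), 0.1)
  expect_gt(sv$n_windows, 1)
  expect_true(all(sv$theta_deg > 0 & sv$theta_deg < 90))
})
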