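test_that("ROI extraction averages the region per frame", {
  st <- toy_stack()
  const <- thermal_stack(array(31.25, c(4, 5, 6)), fps = 30,
                         modality = "MWIR")
  expect_equal(extract_roi_signal(const, rect_roi(1, 1, 4, 5))$values,
               rep(31.25, 6))
  one <- extract_roi_signal(st, rect_roi(2, 3, 2, 3))
  expect_equal(one$values, st$frames[2, 3, ])
  expect_equal(one$fs, st$fps)
  expect_error(extract_roi_signal(st, rect_roi(1, 1, 9, 9)), "outside")
  expect_error(rect_roi(3, 1, 2, 5), "row1 >= row0")
})

test_that("bilateral averaging is the element-wise mean", {
  a <- time_series_signal(c(1, 3), fs = 10)
  b <- time_series_signal(c(3, 1), fs = 10)
  expect_equal(average_bilateral(a, b)$values, c(2, 2))
  expect_equal(average_bilateral(a, a)$values, a$values)
  neg <- time_series_signal(-a$values, fs = 10)
  expect_equal(average_bilateral(a, neg)$values, c(0, 0))
  expect_error(average_bilateral(a, time_series_signal(1:3, fs = 10)),
               "length")
  expect_error(average_bilateral(a, time_series_signal(c(1, 2), fs = 20)),
               "sampling")
})

test_that("bandpass keeps in-band and rejects out-of-band tones", {
  fs <- 60
  inband <- sine_signal(1.2, 40, fs)
  f <- bandpass(inband, 0.8, 1.5)
  core <- (2 * fs):(length(f$values) - 2 * fs)
  expect_gt(sqrt(mean(f$values[core]^2)) / sqrt(mean(inband$values[core]^2)),
            0.95)
  stopb <- sine_signal(0.05, 40, fs)
  g <- bandpass(stopb, 0.1, 0.4)
  expect_lt(sqrt(mean(g$values[core]^2)) / sqrt(mean(stopb$values^2)), 0.10)
  zero <- time_series_signal(rep(0, 600), fs = fs)
  expect_true(all(abs(bandpass(zero, 0.1, 0.4)$values) < 1e-12))
  expect_error(bandpass(inband, 0.5, 40), "passband")
  expect_error(bandpass(time_series_signal(1:8, fs = 60), 0.1, 0.4),
               "too short")
})

test_that("peak detection counts sinusoid crests and honors tie-breaks", {
  s <- sine_signal(0.25, 40, 60)
  pk <- detect_peaks(s, min_separation_s = 1, min_prominence = 0.5)
  expect_length(pk, 10)
  expect_equal(unique(diff(pk)), 240)  # 4 s apart at 60 Hz

  ramp <- time_series_signal(seq_len(100), fs = 10)
  expect_error(detect_peaks(ramp, 1), "fewer than 2")

  # plateau crest: first index of the tied pair, deterministic
  x <- c(0, 1, 2, 2, 1, 0, 0, 1, 3, 1, 0)
  pks <- detect_peaks(time_series_signal(x, fs = 1), min_separation_s = 2)
  expect_equal(pks, c(3L, 9L))

  # invariant to adding a constant; equivariant to time reversal
  s2 <- time_series_signal(s$values + 100, fs = 60)
  expect_equal(detect_peaks(s2, 1, 0.5), pk)
  rev_pk <- detect_peaks(time_series_signal(rev(s$values), fs = 60), 1, 0.5)
  expect_equal(sort(length(s$values) + 1 - rev_pk), pk)
})

test_that("interval-based rates follow 60 / mean interval", {
  expect_equal(rate_from_intervals(c(1, 241, 481), fs = 60)$rate_bpm, 15)
  expect_equal(rate_from_intervals(seq(1, 601, by = 60), fs = 60)$rate_bpm,
               60)
  # intervals 0.8 s and 1.0 s average to 0.9 s
  est <- rate_from_intervals(c(1, 81, 181), fs = 100)
  expect_equal(est$rate_bpm, 60 / 0.9, tolerance = 1e-12)
  expect_error(rate_from_intervals(5, fs = 60), "2 peaks")
})

test_that("spectral rates use raw FFT bins at 1/duration resolution", {
  s <- sine_signal(0.25, 40, 60)
  est <- rate_from_spectrum(s, c(0.1, 0.4))
  expect_equal(est$rate_bpm, 15)  # 0.25 Hz is on-bin for a 40-s record
  expect_equal(est$bin_width_hz, 0.025)
  expect_error(rate_from_spectrum(time_series_signal(rep(2, 2400), fs = 60),
                                  c(0.1, 0.4)), "peak above zero")
  expect_error(rate_from_spectrum(s, c(0.30001, 0.30002)), "bins inside")
  expect_error(rate_from_spectrum(sine_signal(0.25, 10, 60), c(0.1, 0.4)),
               "too short")
})

test_that("time- and frequency-domain rates agree on clean sinusoids", {
  for (f0 in c(0.2, 0.25, 0.3)) {
    s <- sine_signal(f0, 40, 60)
    td <- estimate_rate(s, c(0.1, 0.4), "time_domain")$rate_bpm
    fd <- estimate_rate(s, c(0.1, 0.4), "frequency_domain")$rate_bpm
    expect_lt(abs(td - fd), 1.5 + 1e-9)  # one 0.025 Hz bin
    expect_lt(abs(td - 60 * f0), 0.2)
  }
})

test_that("cycle segmentation and normalization build a template", {
  s <- time_series_signal(sin(2 * pi * (0:200) / 100), fs = 10)
  cyc <- segment_cycles(s, c(1, 101, 201))
  expect_length(cyc, 2)
  expect_length(cyc[[1]], 100)
  expect_error(segment_cycles(s, c(1, 101)), "3 anchors")

  tpl <- normalize_cycles(cyc, n_points = 50)
  expect_equal(tpl$n_cycles, 2)
  expect_length(tpl$mean_waveform, 50)
  expect_true(all(tpl$sd_waveform < 1e-9))  # identical cycles
  expect_gte(min(tpl$mean_waveform), 0)
  expect_lte(max(tpl$mean_waveform), 1)

  one <- normalize_cycles(cyc[1], n_points = 30)
  expect_true(all(one$sd_waveform == 0))

  a <- seq(0, 1, length.out = 40)
  mir <- normalize_cycles(list(a, 1 - a), n_points = 40)
  expect_equal(unname(mir$mean_waveform), rep(0.5, 40), tolerance = 1e-9)

  expect_warning(z <- normalize_cycles(list(a, rep(2, 30))), "zero-amplitude")
  expect_equal(z$n_cycles, 1)
})

test_that("inversion is an involution that swaps peaks and troughs", {
  s <- sine_signal(0.25, 16, 30)
  expect_equal(invert(invert(s))$values, s$values)
  pk <- detect_peaks(s, 1, 0.5)
  tr <- detect_peaks(invert(s), 1, 0.5)
  expect_equal(sort(c(pk, tr)), sort(unique(c(pk, tr))))  # disjoint
  expect_equal(s$values[tr], rep(-1, length(tr)), tolerance = 1e-3)
  z <- time_series_signal(rep(0, 10), fs = 1)
  expect_equal(invert(z)$values, z$values)
})
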