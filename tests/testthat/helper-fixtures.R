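# Small phantom configurations used across tests: 16 s covers four
# respiratory cycles at 15 breaths/min and keeps unit tests fast.
quick_config <- function(duration_s = 16, ...) {
  phantom_config(duration_s = duration_s, ...)
}

# A tiny deterministic stack for I/O and arithmetic tests.
toy_stack <- function(h = 4, w = 5, t = 3, fps = 30, seed = 42) {
  frames <- withr::with_seed(seed, array(runif(h * w * t, 20, 40), c(h, w, t)))
  # quantize so values are exactly representable in float32
  frames <- round(frames * 1024) / 1024
  thermal_stack(frames, fps = fps, pixel_scale = 2e-3, modality = "MWIR",
                origin_note = "toy")
}

sine_signal <- function(freq_hz, duration_s, fs, amp = 1, phase = 0) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  time_series_signal(amp * sin(2 * pi * freq_hz * t + phase), fs = fs)
}

# Brute-force orientation oracle, independent of the gradient-tensor path:
# candidate angles are scored by the summed variance of intensity profiles
# sampled along lines at that angle; streaks are constant along their own
# direction, so the true angle minimizes the score.
oracle_orientation <- function(sti, thetas = seq(2, 88, by = 0.1)) {
  v <- sti$values
  h <- nrow(v); w <- ncol(v)
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  smax <- ceiling(sqrt(h^2 + w^2) / 2)
  svals <- seq(-smax, smax)
  kmax <- smax
  kvals <- seq(-kmax, kmax)
  score <- vapply(thetas, function(th) {
    a <- th * pi / 180
    u <- c(sin(a), cos(a))   # along-streak direction (row, col)
    p <- c(cos(a), -sin(a))  # perpendicular
    tot <- 0; nlines <- 0
    for (k in kvals) {
      rr <- ctr[1] + k * p[1] + svals * u[1]
      cc <- ctr[2] + k * p[2] + svals * u[2]
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      if (sum(ok) < 8) next
      rr <- rr[ok]; cc <- cc[ok]
      r0 <- pmin(floor(rr), h - 1); c0 <- pmin(floor(cc), w - 1)
      fr <- rr - r0; fc <- cc - c0
      prof <- (1 - fr) * (1 - fc) * v[cbind(r0, c0)] +
        fr * (1 - fc) * v[cbind(r0 + 1, c0)] +
        (1 - fr) * fc * v[cbind(r0, c0 + 1)] +
        fr * fc * v[cbind(r0 + 1, c0 + 1)]
      tot <- tot + stats::var(prof) * length(prof)
      nlines <- nlines + length(prof)
    }
    tot / nlines
  }, numeric(1))
  thetas[which.min(score)]
}
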