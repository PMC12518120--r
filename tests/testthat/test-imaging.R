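test_that("Gaussian band-pass has unity centre gain and -6 dB edges", {
  fs <- 32e6; n <- 256
  t <- (seq_len(n) - 1) / fs
  tone <- function(f) rf_frame(matrix(sin(2 * pi * f * t), 1), fs)
  amp <- function(frame, f) {
    y <- bandpass_gaussian(frame, 8e6, 0.5)$samples[1, ]
    2 * Mod(stats::fft(y))[round(f / fs * n) + 1] / n
  }
  expect_equal(amp(tone(8e6), 8e6), 1, tolerance = 1e-6)
  expect_equal(amp(tone(6e6), 6e6), 0.5, tolerance = 1e-6)   # -6 dB
  expect_equal(amp(tone(10e6), 10e6), 0.5, tolerance = 1e-6) # -6 dB

  withr::with_seed(1, {
    wn <- rf_frame(matrix(stats::rnorm(64 * n), 64), fs)
    out <- bandpass_gaussian(wn, 8e6, 0.5)
    spec <- colMeans(t(apply(out$samples, 1,
                             function(r) Mod(stats::fft(r))^2)))
    f <- (seq_len(n) - 1) / n * fs
    expect_lt(abs(f[which.max(spec[1:(n / 2)])] - 8e6), 1e6)
  })
  expect_error(bandpass_gaussian(tone(8e6), 15e6, 0.5), "Nyquist")
})

test_that("delay-and-sum localizes an on-axis scatterer and matches brute force", {
  expect_true(all(das_beamform(
    rf_frame(matrix(0, 8, 64), 32e6), transducer_array(8),
    image_grid(transducer_array(8)$element_x,
               seq(1e-3, 2e-3, length.out = 4)),
    1480) == 0))

  # full 32-element aperture: the point-spread function is narrow enough
  # to pin the argmax to the scatterer position
  arr <- transducer_array()
  acq <- quiet_acq(1800L)
  frame <- generate_rf(us_phantom(0, 37e-3), arr, acq)
  grid <- default_image_grid(arr, acq, z_range = c(35e-3, 39e-3))
  img <- das_beamform(frame, arr, grid, 1480)
  env <- envelope_detect(img)
  pk <- which(env == max(env), arr.ind = TRUE)[1, ]  # symmetric ties ok
  dz <- 1480 / (2 * 32e6)
  expect_lte(abs(grid$z_coords[pk[1]] - 37e-3), dz)
  expect_lte(abs(grid$x_coords[pk[2]] - 0), arr$pitch)

  # oracle: per-pixel per-element loop on a 16x16 grid, small aperture
  arr8 <- transducer_array(n_elements = 8)
  frame8 <- generate_rf(us_phantom(0, 37e-3), arr8, quiet_acq(1700L))
  small <- image_grid(seq(-0.6e-3, 0.6e-3, length.out = 16),
                      seq(36e-3, 38e-3, length.out = 16))
  fast <- das_beamform(frame8, arr8, small, 1480)
  slow <- das_brute_force(frame8, arr8, small, 1480)
  expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-9)
})

test_that("the multiplexed firing schedule beamforms like the full aperture", {
  arr <- transducer_array(n_elements = 8)
  frame <- generate_rf(three_wire_phantom(), arr, quiet_acq())
  grid <- image_grid(arr$element_x, seq(33e-3, 41e-3, length.out = 48))
  full <- das_beamform(frame, arr, grid, 1480)
  firings <- mux_acquisition(frame, 4, 2)
  expect_equal(das_beamform(firings, arr, grid, 1480), full,
               tolerance = 1e-12)
  # a schedule that misses elements is rejected
  expect_error(das_beamform(firings[-1], arr, grid, 1480), "cover")
})

test_that("envelope detection recovers amplitude and modulation", {
  t <- seq(0, 1, length.out = 1024)
  x <- 0.8 * sin(2 * pi * 40 * t)
  env <- envelope_detect(x)
  interior <- 100:924
  expect_equal(max(abs(env[interior] - 0.8)), 0, tolerance = 0.02)
  expect_true(all(env >= 0))
  expect_true(all(envelope_detect(numeric(64)) == 0))

  g <- exp(-(t - 0.5)^2 / (2 * 0.05^2))
  gm <- g * sin(2 * pi * 60 * t)
  rec <- envelope_detect(gm)
  expect_lt(max(abs(rec[interior] - g[interior]) / max(g)), 0.02)
})

test_that("log compression normalizes to 0 dB and clips at the range floor", {
  expect_true(all(log_compress_display(matrix(3, 4, 4))$values_db == 0))
  img <- matrix(c(1, 1e-3, 0.5, 1e-6), 2, 2)
  bm <- log_compress_display(img, 30)
  expect_equal(bm$values_db[1, 1], 0)
  expect_equal(bm$values_db[2, 1], -30)   # 20log10(1e-3) = -60, clipped
  expect_equal(bm$values_db[1, 2], 20 * log10(0.5))
  expect_error(log_compress_display(matrix(0, 2, 2)), "all-zero")
  expect_error(log_compress_display(matrix(-1, 2, 2)), "non-negative")
})

test_that("frame averaging is the arithmetic mean with sqrt(N) noise gain", {
  base <- matrix(sin(seq_len(64)), 4, 16)
  f <- rf_frame(base, 32e6)
  expect_equal(average_frames(rep(list(f), 10))$samples, base)
  expect_true(all(average_frames(list(
    f, rf_frame(-base, 32e6)))$samples == 0))

  withr::with_seed(2, {
    frames <- lapply(1:10, function(k)
      rf_frame(matrix(stats::rnorm(8000), 4), 32e6))
    avg <- average_frames(frames)
    expect_equal(stats::sd(avg$samples), 1 / sqrt(10), tolerance = 0.1)
  })
  expect_error(average_frames(list()), "empty")
  expect_error(average_frames(list(f, rf_frame(matrix(0, 2, 2), 32e6))),
               "dimensions")
})

test_that("display output is invariant to a global RF scale", {
  arr <- transducer_array(n_elements = 8)
  frame <- generate_rf(three_wire_phantom(), arr, quiet_acq())
  grid <- image_grid(arr$element_x, seq(33e-3, 41e-3, length.out = 64))
  b1 <- reconstruct_bmode(frame, arr, grid)
  scaled <- rf_frame(7.3 * frame$samples, frame$sample_rate)
  b2 <- reconstruct_bmode(scaled, arr, grid)
  expect_equal(b1$values_db, b2$values_db, tolerance = 1e-9)
  expect_equal(max(b1$values_db), 0)
})

test_that("bright-maxima search returns separated peaks bright to dim", {
  v <- matrix(-30, 40, 10)
  v[10, 5] <- 0; v[25, 5] <- -3; v[33, 7] <- -8
  v[11, 5] <- -1            # shoulder of the first peak: not a maximum
  bm <- structure(list(values_db = v, dynamic_range_db = 30,
                       grid = image_grid(seq(1e-3, 10e-3, length.out = 10),
                                         seq(30e-3, 43e-3, length.out = 40))),
                  class = "bmode_image")
  pk <- find_bright_maxima(bm, 3, min_separation_m = 1e-3)
  expect_equal(nrow(pk), 3)
  expect_equal(pk$db, c(0, -3, -8))
})

test_that("the TX-coupling burst saturates early samples and blanking removes it", {
  arr <- transducer_array(n_elements = 8)
  acq_art <- acquisition_config(n_samples = 1800L, noise_snr_db = Inf,
                                tx_artifact_amplitude = 2)
  dirty <- generate_rf(three_wire_phantom(), arr, acq_art)
  clean <- generate_rf(three_wire_phantom(), arr, quiet_acq(1800L))
  tx_window <- seq_len(ceiling(5 * 132e-9 * 32e6) + 1)
  expect_gt(max(abs(dirty$samples[, tx_window])),
            1.9 * max(abs(clean$samples)))
  # outside the burst the signals are identical
  expect_equal(dirty$samples[, -tx_window], clean$samples[, -tx_window])

  grid <- image_grid(arr$element_x, seq(33e-3, 41e-3, length.out = 64))
  b_dirty <- reconstruct_bmode(dirty, arr, grid, blank_interval_s = 1e-6)
  b_clean <- reconstruct_bmode(clean, arr, grid)
  expect_equal(b_dirty$values_db, b_clean$values_db, tolerance = 1e-9)
})
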