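test_that("level grid spans the documented signed code book", {
  g <- level_grid(11, 2, 0)
  expect_equal(g$levels, 2^(-10:0))
  expect_equal(2L * g$n_levels, 22L)                   # signed codes
  expect_equal(20 * log10(max(g$levels) / min(g$levels)), 60.20600,
               tolerance = 1e-6)                       # ~60 dB range
  expect_equal(level_grid(2, 2, 0)$levels, c(0.5, 1))
  expect_error(level_grid(11, base = 1), "> 1")
  expect_error(level_grid(1), ">= 2")
})

test_that("normalization is symmetric around the mean and invertible", {
  x <- c(0, 0.25, 0.5, 0.75, 1)                        # mean 0.5
  nrm <- normalize_rf(x)
  expect_equal(nrm$offset, 0.5)
  expect_equal(range(nrm$x), c(-1, 1))
  expect_equal(mean(nrm$x), 0)
  expect_equal(denormalize_rf(nrm$x, nrm), x)

  y <- c(-1, 0.3, 1, -0.2)                             # zero mean? no
  z <- y - mean(y)
  z <- z / max(abs(z))                                 # already normalized
  nrm2 <- normalize_rf(z)
  expect_equal(nrm2$x, z)
  expect_equal(nrm2$scale, 1)

  sinus <- 0.37 * sin(seq(0, 4 * pi, length.out = 128))
  expect_equal(normalize_rf(sinus)$scale, 1 / 0.37, tolerance = 1e-3)
  expect_error(normalize_rf(rep(2, 10)), "constant")
})

test_that("encoder toggles on a constant, ramps on an exponential, clamps at the floor", {
  g <- level_grid(11, 2, 0)
  # constant input exactly at a grid level: after lock-on the tracked
  # level toggles between the two nearest levels
  x <- rep(2^-4, 40)
  st <- logdelta_encode(x, g, initial_level = -4L)
  expect_identical(st$delta_bits[1:6], c(0L, 1L, 0L, 1L, 0L, 1L))
  expect_true(all(st$levels %in% c(-5L, -4L)))

  # slow exponential magnitude sweep ramps Y through all 11 levels per
  # polarity; the sign pattern (period 3, so it does not phase-lock with
  # the period-2 level toggle) exercises every signed code
  n <- 402
  mag <- 2^seq(-10.5, 0, length.out = n)
  sweep <- mag * rep(c(1, 1, -1), length.out = n)
  st2 <- logdelta_encode(sweep, g, initial_level = "min")
  expect_setequal(unique(st2$levels), -10:0)
  expect_setequal(unique(st2$sign_bits), c(1L, 0L))
  # 22 distinct signed codes visited
  expect_equal(length(unique(paste(st2$sign_bits, st2$levels))), 22L)

  # input below the smallest level: pinned at the grid minimum
  st3 <- logdelta_encode(rep(2^-14, 16), g, initial_level = "min")
  expect_true(all(st3$delta_bits == 0L))
  expect_true(all(st3$levels == g$y_min))

  expect_error(logdelta_encode(x, g, initial_level = 3L), "initial_level")
})

test_that("decoder reproduces sign * base^Y and replays the encoder", {
  g <- level_grid(11, 2, 0)
  mk <- function(delta, sign, init) {
    structure(list(delta_bits = delta, sign_bits = sign,
                   initial_level = init, grid = g,
                   n_samples = length(delta)),
              class = "coded_stream")
  }
  # one step up from Y = -1 lands on Y = 0: D = +2^0 = 1
  expect_equal(logdelta_decode(mk(1L, 1L, -1L)), 1)
  # one step down from Y = -2 lands on Y = -3: D = -2^-3 = -0.125
  expect_equal(logdelta_decode(mk(0L, 0L, -2L)), -0.125)

  # decode replays encode's level recursion bit-for-bit
  x <- random_normalized_signal(800, seed = 4)
  st <- logdelta_encode(x, g)
  rec <- logdelta_decode(st)
  expect_equal(rec, ifelse(st$sign_bits == 1, 1, -1) * g$base^st$levels)

  # constant at a grid level: reconstruction alternates level/neighbour;
  # log-domain running mean within half a grid step of the input
  st4 <- logdelta_encode(rep(2^-4, 64), g, initial_level = -4L)
  rec4 <- logdelta_decode(st4)
  expect_setequal(unique(rec4), c(2^-5, 2^-4))
  gm <- mean(log2(abs(rec4)))
  expect_lt(abs(gm - (-4)), 0.5 + 1e-9)
})

test_that("tracked level moves by exactly one step outside clamp boundaries", {
  g <- level_grid(8, 2, 0)
  for (seed in 1:5) {
    x <- random_normalized_signal(300, seed = seed)
    st <- logdelta_encode(x, g)
    y <- c(st$initial_level, st$levels)
    step <- diff(y)
    at_clamp <- (y[-length(y)] == g$y_min & step == 0) |
      (y[-length(y)] == g$y_max & step == 0)
    expect_true(all(abs(step) == 1 | at_clamp))
  }
})

test_that("serialization costs exactly 2 bits/sample and round-trips", {
  g <- level_grid(11, 2, 0)
  for (n in c(1, 7, 8, 500)) {
    x <- random_normalized_signal(512, seed = n)[seq_len(n)]
    st <- logdelta_encode(x, g)
    bytes <- serialize_stream(st)
    expect_identical(length(bytes), as.integer(ceiling(2 * n / 8)))
    back <- deserialize_stream(bytes, n, g, st$initial_level)
    expect_identical(back$delta_bits, st$delta_bits)
    expect_identical(back$sign_bits, st$sign_bits)
    expect_equal(logdelta_decode(back), logdelta_decode(st))
  }
  expect_error(deserialize_stream(as.raw(1), 100, g), "shorter")
})

test_that("delta codec tracks the memoryless log quantizer on slew-limited signals", {
  g <- level_grid(11, 2, 0)
  # log-magnitude changes by < 1 grid step (factor 2) per sample
  n <- 600
  mag <- 2^(-5 + 4 * sin(seq(0, 3 * pi, length.out = n)) *
              seq(0, 1, length.out = n))
  x <- mag * sign(sin(seq_len(n)))
  x[x == 0] <- mag[x == 0]
  rec <- logdelta_decode(logdelta_encode(x, g, initial_level = -5L))
  memoryless <- quantize_log_memoryless(x, g)
  # within one grid step at every sample once past initial convergence
  lag <- 8
  ratio <- abs(rec[-(1:lag)]) / abs(memoryless[-(1:lag)])
  expect_true(all(ratio <= 2 + 1e-12 & ratio >= 0.5 - 1e-12))
})

test_that("uniform quantization meets its half-step error bound", {
  # step midpoints realize the worst case exactly: half of 1/1023
  mids <- ((0:1022) + 0.5) / 1023
  q <- quantize_linear(mids, 2^10)
  expect_equal(max(abs(q$values - mids)), 1 / 2046, tolerance = 1e-9)

  on_grid <- (0:31) / 31
  expect_equal(quantize_linear(on_grid, 32)$values, on_grid)
  expect_true(all(quantize_linear(c(0.2, 0.7), 2)$values %in% c(0, 1)))

  withr::with_seed(7, {
    x <- stats::runif(1e5)
    for (n_levels in c(2^5, 2^10, 2^15)) {
      q <- quantize_linear(x, n_levels)
      expect_lte(max(abs(q$values - x)), 1 / (2 * (n_levels - 1)) + 1e-15)
      expect_true(all(q$codes >= 0 & q$codes <= n_levels - 1))
    }
  })
  expect_error(quantize_linear(c(0.5), 1), ">= 2")
  expect_error(quantize_linear(c(-0.1, 0.5), 4), "\\[0, 1\\]")
})

test_that("memoryless log quantization rounds in the log domain, ties upward", {
  g <- level_grid(11, 2, 0)
  expect_equal(quantize_log_memoryless(g$levels, g), g$levels)
  # geometric midpoint of 2^-3 and 2^-2 rounds to the upper level
  expect_equal(quantize_log_memoryless(2^-2.5, g), 2^-2)
  expect_equal(quantize_log_memoryless(-2^-2.5, g), -2^-2)
  # sign preserved, magnitudes clamped to the grid
  x <- c(-1, -0.001, 0.3, 2)
  q <- quantize_log_memoryless(x, g)
  expect_equal(sign(q), c(-1, -1, 1, 1))
  expect_true(all(abs(q) %in% g$levels))
})

test_that("delta statistics reproduce the 60-code / 6-bit arithmetic", {
  withr::with_seed(3, {
    codes <- as.integer(round(511 + 100 * sin(1:200) +
                                stats::rnorm(200, sd = 10)))
    codes <- pmin(pmax(codes, 0L), 1023L)
    ds <- delta_stats(codes, 1024)
    expect_equal(ds$max_abs_code_difference,
                 max(abs(diff(codes))))          # brute force over pairs
  })
  ds60 <- delta_stats(c(500L, 560L), 1024)
  expect_equal(ds60$bits_required, 6)
  expect_equal(ds60$reduction_fraction, 0.40)
  expect_equal(delta_stats(rep(7L, 5), 1024)$max_abs_code_difference, 0)
  expect_equal(delta_stats(rep(7L, 5), 1024)$bits_required, 1)
  expect_equal(delta_stats(c(0L, 5L, 3L), 1024)$bits_required, 3)
  expect_error(delta_stats(integer(0), 1024), "empty")
})

test_that("compression ratio is the plain bit quotient", {
  expect_equal(compression_ratio(10, 2), 5)
  expect_equal(compression_ratio(10, 10), 1)
  expect_equal(compression_ratio(12, 3), 4)
  expect_error(compression_ratio(0, 2), "> 0")
})
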