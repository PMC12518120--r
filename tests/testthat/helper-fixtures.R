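# Shared fixtures built in code at test time.

# Single-element array centred at x = 0: isolates on-axis geometry.
single_element_array <- function() transducer_array(n_elements = 1)

# Noiseless default acquisition (deterministic signal only).
quiet_acq <- function(n_samples = 2048L, seed = NULL)
  acquisition_config(n_samples = n_samples, noise_snr_db = Inf, seed = seed)

# The standard study scene: three wires plus diffuse background
# scatterers over the imaging window.
study_phantom <- function(arr, seed = 1L, n_diffuse = 150L) {
  add_diffuse_scatterers(
    three_wire_phantom(), n_diffuse,
    x_range = range(arr$element_x), z_range = c(30e-3, 43e-3),
    mean_reflectivity = 0.03, seed = seed)
}

# A small band-limited random signal normalized for codec tests.
random_normalized_signal <- function(n = 512, seed = 1) {
  withr::with_seed(seed, {
    x <- stats::rnorm(n)
    k <- stats::filter(x, rep(1 / 8, 8), sides = 2)
    k[is.na(k)] <- 0
    normalize_rf(as.numeric(k) + 1e-9 * seq_len(n))$x
  })
}

# Independent brute-force delay-and-sum: per-pixel, per-element loop
# using approx() interpolation. Oracle for das_beamform().
das_brute_force <- function(frame, array, grid, sound_speed) {
  nz <- length(grid$z_coords); nx <- length(grid$x_coords)
  ns <- ncol(frame$samples)
  t_axis <- frame$t0 + (seq_len(ns) - 1) / frame$sample_rate
  img <- matrix(0, nz, nx)
  for (i in seq_len(nz)) for (j in seq_len(nx)) {
    z <- grid$z_coords[i]; x <- grid$x_coords[j]
    acc <- 0
    for (r in seq_len(nrow(frame$samples))) {
      xe <- array$element_x[frame$elements[r]]
      tau <- (z + sqrt((x - xe)^2 + z^2)) / sound_speed
      # linear interpolation, zero outside the window (match the
      # implementation's i0 >= 1 & i0 < ns support exactly)
      pos <- (tau - frame$t0) * frame$sample_rate + 1
      if (pos >= 1 && floor(pos) < ns) {
        v <- stats::approx(t_axis, frame$samples[r, ], xout = tau)$y
        acc <- acc + v
      }
    }
    img[i, j] <- acc
  }
  img
}

# Independent global-moment SSIM using R's sample-moment routines; the
# sample/population normalization cancels in the ratio.
ssim_reference <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  mx <- mean(x); my <- mean(y)
  (2 * mx * my * 2 * stats::cov(x, y)) /
    ((mx^2 + my^2) * (stats::var(x) + stats::var(y)))
}
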