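# Plane-wave point-scatterer RF simulator.
#
# Physics model: a single unfocused plane wave at normal incidence travels
# straight down, reaches a scatterer at depth z after z/c, and the echo
# returns to element e over the direct path r = sqrt((x_s - x_e)^2 + z^2),
# giving the two-way delay tau = (z + r)/c. The received waveform is a
# band-limited replica of the transmit pulse scaled by reflectivity,
# 1/r^k spreading and round-trip frequency-dependent attenuation.

# Gaussian envelope std dev (seconds) that puts the -6 dB points of the
# pulse amplitude spectrum at f0 * (1 +- fbw/2).
.pulse_sigma_t <- function(f0, fractional_bandwidth) {
  sigma_f <- fractional_bandwidth * f0 / (2 * sqrt(2 * log(2)))
  1 / (2 * pi * sigma_f)
}

# Continuous-time pulse used by the simulator: Gaussian envelope peaking at
# t = 0 with a cosine carrier, gated to the tx_cycles * tx_period support.
# Peak amplitude 1 at t = 0.
.pulse_eval <- function(t, f0, fractional_bandwidth, duration) {
  sigma_t <- .pulse_sigma_t(f0, fractional_bandwidth)
  out <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * t)
  out[abs(t) > duration / 2] <- 0
  out
}

#' Sampled transmit/receive excitation pulse
#'
#' A zero-mean band-limited pulse: a gated sinusoid at `1/tx_period`
#' smoothed by a Gaussian envelope whose -6 dB spectral width equals the
#' transducer fractional bandwidth, normalized to peak amplitude 1. This is
#' the waveform a scatterer echo injects into each receive channel.
#'
#' @param tx_cycles Number of carrier cycles (0 gives an all-zero, empty
#'   waveform).
#' @param tx_period Carrier period in seconds.
#' @param sample_rate Sample rate in Hz.
#' @param fractional_bandwidth Fractional -6 dB bandwidth shaping the
#'   envelope (default 0.78).
#' @return Numeric vector of `round(tx_cycles * tx_period * sample_rate)`
#'   samples.
#' @examples
#' p <- excitation_pulse(5, 132e-9, 32e6)
#' length(p)   # 21 samples = 660 ns at 32 MS/s
#' @export
excitation_pulse <- function(tx_cycles, tx_period, sample_rate,
                             fractional_bandwidth = 0.78) {
  if (tx_period <= 0 || sample_rate <= 0)
    stop("`tx_period` and `sample_rate` must be > 0", call. = FALSE)
  if (tx_period <= 2 / sample_rate)
    stop("`tx_period` must exceed two sample intervals (Nyquist)",
         call. = FALSE)
  if (tx_cycles < 0) stop("`tx_cycles` must be >= 0", call. = FALSE)
  duration <- tx_cycles * tx_period
  n <- round(duration * sample_rate)
  if (n == 0) return(numeric(0))
  t <- (seq_len(n) - 1) / sample_rate
  f0 <- 1 / tx_period
  sigma_t <- .pulse_sigma_t(f0, fractional_bandwidth)
  # sine carrier + envelope symmetric about the gate centre => zero mean
  p <- exp(-(t - duration / 2)^2 / (2 * sigma_t^2)) * sin(2 * pi * f0 * t)
  p / max(abs(p))
}

#' Simulate the RF frame of one plane-wave firing
#'
#' Generates the per-element receive signals for a point-scatterer phantom
#' insonified by a single plane wave at normal incidence. Each scatterer
#' contributes a delayed band-limited pulse with amplitude
#' `reflectivity / r^k * 10^(-att_db/20)`, where `r` is the element-to-
#' scatterer range, `k` the spreading exponent and `att_db` the round-trip
#' attenuation from [tissue_attenuation_db()] evaluated at the array centre
#' frequency (coefficient 0 models water). White Gaussian noise is then
#' added so that the ratio of the peak signal amplitude to the noise
#' standard deviation equals `noise_snr_db`.
#'
#' @param phantom A [us_phantom()].
#' @param array A [transducer_array()].
#' @param acq An [acquisition_config()]; its `seed` makes the noise
#'   reproducible.
#' @return An [rf_frame()] of dimension `n_elements` x `n_samples`, `t0 = 0`.
#' @examples
#' frame <- generate_rf(three_wire_phantom(), transducer_array(),
#'                      acquisition_config(noise_snr_db = Inf))
#' # first wire echo near 2 * 34 mm / 1480 m/s ~ 45.9 us
#' which.max(abs(frame$samples[16, ])) / 32e6 * 1e6
#' @export
generate_rf <- function(phantom, array, acq) {
  stopifnot(inherits(phantom, "us_phantom"),
            inherits(array, "transducer_array"),
            inherits(acq, "acquisition_config"))
  fs <- acq$sample_rate
  n <- acq$n_samples
  c0 <- acq$sound_speed
  f0 <- array$center_frequency
  fbw <- array$fractional_bandwidth_6db
  duration <- acq$tx_cycles * acq$tx_period
  samples <- matrix(0, nrow = array$n_elements, ncol = n)
  t_axis <- (seq_len(n) - 1) / fs

  if (nrow(phantom) > 0 && acq$tx_cycles > 0) {
    t_max <- (n - 1) / fs
    for (s in seq_len(nrow(phantom))) {
      zs <- phantom$z[s]; xs <- phantom$x[s]
      refl <- phantom$reflectivity[s]
      if (refl == 0) next
      att_db <- tissue_attenuation_db(f0 / 1e6, zs * 100,
                                      acq$attenuation_db_mhz_cm,
                                      round_trip = TRUE)
      att <- 10^(-att_db / 20)
      r <- sqrt((xs - array$element_x)^2 + zs^2)
      tau <- (zs + r) / c0
      if (min(tau) - duration / 2 > t_max) {
        warning(sprintf(
          "scatterer %d at z = %.1f mm arrives after the recorded window; truncated",
          s, zs * 1e3), call. = FALSE)
        next
      }
      amp <- refl * att / r^acq$spreading_exponent
      for (e in seq_len(array$n_elements)) {
        # restrict to the pulse support around the arrival time
        i0 <- max(1L, floor((tau[e] - duration / 2 - acq$t0 %||% 0) * fs) + 1L)
        i1 <- min(n, ceiling((tau[e] + duration / 2) * fs) + 1L)
        if (i0 > i1) next
        idx <- i0:i1
        samples[e, idx] <- samples[e, idx] +
          amp[e] * .pulse_eval(t_axis[idx] - tau[e], f0, fbw, duration)
      }
    }
  }

  if (acq$tx_artifact_amplitude > 0 && acq$tx_cycles > 0) {
    # electrical TX-to-readout coupling: a saturated (clipped) burst in
    # every channel while the transmitter fires
    peak <- max(abs(samples))
    if (peak == 0) peak <- 1
    idx <- which(t_axis <= duration)
    burst <- sign(sin(2 * pi * t_axis[idx] / acq$tx_period))
    samples[, idx] <- samples[, idx] +
      matrix(acq$tx_artifact_amplitude * peak * burst,
             nrow = nrow(samples), ncol = length(idx), byrow = TRUE)
  }

  if (is.finite(acq$noise_snr_db)) {
    peak <- max(abs(samples))
    if (peak == 0) peak <- 1
    sigma <- peak / 10^(acq$noise_snr_db / 20)
    noise <- function() matrix(stats::rnorm(length(samples), sd = sigma),
                               nrow = nrow(samples))
    samples <- samples +
      if (is.null(acq$seed)) noise() else withr::with_seed(acq$seed, noise())
  }

  rf_frame(samples, sample_rate = fs, t0 = 0,
           element_x = array$element_x, sound_speed = c0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a frame into the firing schedule of a multiplexed acquisition
#'
#' With `mux_ratio`:1 multiplexers in front of `n_frontends` silicon
#' front-ends, only one element per multiplexer is read out per firing, so
#' covering the aperture takes `mux_ratio` plane-wave transmissions.
#' Firing `k` (1-based) selects element `k + mux_ratio * (m - 1)` for
#' front-end `m`: each front-end owns a contiguous block of `mux_ratio`
#' elements and steps through it one firing at a time. The union of all
#' firings covers every element exactly once.
#'
#' @param frame An [rf_frame()] covering the full aperture.
#' @param mux_ratio Inputs per multiplexer (e.g. 8).
#' @param n_frontends Number of front-ends; `mux_ratio * n_frontends` must
#'   equal the number of rows of `frame`.
#' @return List of `mux_ratio` [rf_frame()] objects, each with
#'   `n_frontends` rows and an `elements` field naming the selected array
#'   elements.
#' @examples
#' f <- rf_frame(matrix(0, 32, 8), 32e6)
#' sched <- mux_acquisition(f, 8, 4)
#' length(sched)              # 8 firings
#' sched[[1]]$elements        # 1  9 17 25
#' @export
mux_acquisition <- function(frame, mux_ratio, n_frontends) {
  stopifnot(inherits(frame, "rf_frame"))
  mux_ratio <- as.integer(mux_ratio)
  n_frontends <- as.integer(n_frontends)
  n_el <- nrow(frame$samples)
  if (mux_ratio < 1L || n_frontends < 1L ||
      mux_ratio * n_frontends != n_el)
    stop(sprintf("mux_ratio (%d) x n_frontends (%d) must equal n_elements (%d)",
                 mux_ratio, n_frontends, n_el), call. = FALSE)
  lapply(seq_len(mux_ratio), function(k) {
    els <- k + mux_ratio * (seq_len(n_frontends) - 1L)
    rf_frame(frame$samples[els, , drop = FALSE], frame$sample_rate,
             t0 = frame$t0, elements = frame$elements[els],
             element_x = frame$element_x, sound_speed = frame$sound_speed)
  })
}

#' Inject channel-to-channel crosstalk into a frame
#'
#' Adds to every channel copies of the other channels scaled by the
#' amplitude coupling factor `10^(dB/20)` — `adjacent_db` for the two
#' nearest neighbours and `distant_db` for all other channels.
#'
#' @param frame An [rf_frame()].
#' @param spec A [crosstalk_spec()].
#' @return An [rf_frame()] of identical dimensions.
#' @export
apply_crosstalk <- function(frame, spec) {
  stopifnot(inherits(frame, "rf_frame"), inherits(spec, "crosstalk_spec"))
  a <- 10^(spec$adjacent_db / 20)
  d <- 10^(spec$distant_db / 20)
  x <- frame$samples
  n <- nrow(x)
  if (n > 1 && (a > 0 || d > 0)) {
    # coupling matrix: identity + a on the first off-diagonals + d elsewhere
    couple <- matrix(d, n, n)
    diag(couple) <- 1
    idx <- seq_len(n - 1)
    couple[cbind(idx, idx + 1)] <- a
    couple[cbind(idx + 1, idx)] <- a
    x <- couple %*% x
  }
  rf_frame(x, frame$sample_rate, t0 = frame$t0, elements = frame$elements,
           element_x = frame$element_x, sound_speed = frame$sound_speed)
}
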