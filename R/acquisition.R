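#' Linear receive array geometry
#'
#' Describes a 1-D receive aperture of evenly pitched elements centred on
#' the lateral origin. The defaults correspond to the flexible prototype the
#' package models: 32 receive elements at 180 um pitch, 8.2 MHz centre
#' frequency and a 78 % fractional bandwidth at -6 dB.
#'
#' @param n_elements Number of receive elements (>= 1).
#' @param pitch Element pitch in metres.
#' @param center_frequency Transducer centre frequency in Hz.
#' @param fractional_bandwidth_6db Fractional -6 dB bandwidth (0, 2).
#' @return An object of class `transducer_array` with fields `n_elements`,
#'   `pitch`, `center_frequency`, `fractional_bandwidth_6db` and `element_x`
#'   (lateral element positions in metres, strictly increasing, centred on 0).
#' @examples
#' arr <- transducer_array()
#' range(arr$element_x)     # +- 2.79 mm aperture
#' @export
transducer_array <- function(n_elements = 32L,
                             pitch = 180e-6,
                             center_frequency = 8.2e6,
                             fractional_bandwidth_6db = 0.78) {
  stopifnot(length(n_elements) == 1L, length(pitch) == 1L)
  n_elements <- as.integer(n_elements)
  if (is.na(n_elements) || n_elements < 1L)
    stop("`n_elements` must be a positive integer", call. = FALSE)
  if (!is.finite(pitch) || pitch <= 0)
    stop("`pitch` must be > 0", call. = FALSE)
  if (!is.finite(center_frequency) || center_frequency <= 0)
    stop("`center_frequency` must be > 0", call. = FALSE)
  if (fractional_bandwidth_6db <= 0 || fractional_bandwidth_6db >= 2)
    stop("`fractional_bandwidth_6db` must lie in (0, 2)", call. = FALSE)
  element_x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  structure(
    list(n_elements = n_elements, pitch = pitch,
         center_frequency = center_frequency,
         fractional_bandwidth_6db = fractional_bandwidth_6db,
         element_x = element_x),
    class = "transducer_array")
}

#' Acquisition timing, sampling and noise parameters
#'
#' @param sample_rate ADC sample rate in Hz.
#' @param n_samples Samples recorded per element per firing.
#' @param sound_speed Medium sound speed in m/s; the default 1480 m/s is
#'   water at room temperature.
#' @param tx_cycles Number of cycles in the transmit pulse train.
#' @param tx_period Transmit pulse period in seconds.
#' @param noise_snr_db Peak-signal-to-noise ratio of the additive white
#'   Gaussian receiver noise in dB; `Inf` disables noise.
#' @param attenuation_db_mhz_cm Frequency-dependent propagation attenuation
#'   coefficient in dB/(MHz*cm); 0 (the default) models water, 0.7 is a
#'   typical soft-tissue value.
#' @param spreading_exponent Exponent of the 1/range^k receive spreading
#'   loss (default 1).
#' @param tx_artifact_amplitude Amplitude (relative to the strongest echo)
#'   of the saturated electrical transmit-coupling burst injected into
#'   every channel during the transmit window; 0 (default) disables it.
#'   Excluded from imaging with the `blank_interval_s` argument of
#'   [reconstruct_bmode()].
#' @param seed Integer seed making the simulated noise reproducible, or
#'   `NULL` to draw from the session RNG stream.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sample_rate = 32e6,
                               n_samples = 2048L,
                               sound_speed = 1480,
                               tx_cycles = 5L,
                               tx_period = 132e-9,
                               noise_snr_db = Inf,
                               attenuation_db_mhz_cm = 0,
                               spreading_exponent = 1,
                               tx_artifact_amplitude = 0,
                               seed = NULL) {
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("`sample_rate` must be > 0", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("`n_samples` must be >= 1", call. = FALSE)
  if (!is.finite(sound_speed) || sound_speed <= 0)
    stop("`sound_speed` must be > 0", call. = FALSE)
  if (tx_cycles < 0) stop("`tx_cycles` must be >= 0", call. = FALSE)
  if (!is.finite(tx_period) || tx_period <= 0)
    stop("`tx_period` must be > 0", call. = FALSE)
  if (attenuation_db_mhz_cm < 0)
    stop("`attenuation_db_mhz_cm` must be >= 0", call. = FALSE)
  structure(
    list(sample_rate = sample_rate, n_samples = n_samples,
         sound_speed = sound_speed, tx_cycles = as.integer(tx_cycles),
         tx_period = tx_period, noise_snr_db = noise_snr_db,
         attenuation_db_mhz_cm = attenuation_db_mhz_cm,
         spreading_exponent = spreading_exponent,
         tx_artifact_amplitude = tx_artifact_amplitude,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "acquisition_config")
}

#' Point/wire scatterer phantom
#'
#' A scene is a set of point scatterers (a thin wire imaged in cross-section
#' behaves as one). Coordinates: `x` lateral (metres, array centred on 0),
#' `z` depth (metres, positive into the medium).
#'
#' @param x,z,reflectivity Equal-length numeric vectors of lateral position
#'   (m), depth (m, > 0) and dimensionless reflectivity (>= 0).
#' @return An object of class `us_phantom`: a data frame with columns
#'   `x`, `z`, `reflectivity`.
#' @examples
#' three_wire_phantom()
#' @export
us_phantom <- function(x, z, reflectivity = rep(1, length(x))) {
  if (length(x) != length(z) || length(z) != length(reflectivity))
    stop("`x`, `z`, `reflectivity` must have equal length", call. = FALSE)
  if (length(z) && (any(!is.finite(z)) || any(z <= 0)))
    stop("all scatterer depths must be finite and > 0", call. = FALSE)
  if (length(reflectivity) &&
      (any(!is.finite(reflectivity)) || any(reflectivity < 0)))
    stop("reflectivity must be finite and >= 0", call. = FALSE)
  structure(data.frame(x = as.numeric(x), z = as.numeric(z),
                       reflectivity = as.numeric(reflectivity)),
            class = c("us_phantom", "data.frame"))
}

#' Three copper-wire validation phantom
#'
#' On-axis wires at 34, 37 and 40 mm depth, the standard water-tank
#' validation scene for this system.
#'
#' @param depths_m Wire depths in metres.
#' @param reflectivity Per-wire reflectivity.
#' @return A [us_phantom()].
#' @export
three_wire_phantom <- function(depths_m = c(34e-3, 37e-3, 40e-3),
                               reflectivity = rep(1, length(depths_m))) {
  us_phantom(x = rep(0, length(depths_m)), z = depths_m,
             reflectivity = reflectivity)
}

#' Add diffuse sub-resolution scatterers to a phantom
#'
#' Sprinkles weak random scatterers over a rectangular region to emulate
#' speckle-generating tissue background around the bright targets.
#'
#' @param phantom A [us_phantom()].
#' @param n Number of diffuse scatterers.
#' @param x_range,z_range Lateral/depth extent in metres (length-2).
#' @param mean_reflectivity Mean reflectivity of a diffuse scatterer;
#'   amplitudes are drawn as `|N(0, 1)|` scaled to this mean.
#' @param seed Integer seed, or `NULL`.
#' @return A [us_phantom()] with `n` extra rows.
#' @export
add_diffuse_scatterers <- function(phantom, n,
                                   x_range, z_range,
                                   mean_reflectivity = 0.03,
                                   seed = NULL) {
  stopifnot(inherits(phantom, "us_phantom"), n >= 0)
  if (n == 0) return(phantom)
  draw <- function() {
    data.frame(
      x = stats::runif(n, x_range[1], x_range[2]),
      z = stats::runif(n, z_range[1], z_range[2]),
      reflectivity = abs(stats::rnorm(n)) * mean_reflectivity /
        sqrt(2 / pi))
  }
  extra <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  us_phantom(c(phantom$x, extra$x), c(phantom$z, extra$z),
             c(phantom$reflectivity, extra$reflectivity))
}

#' Per-element RF frame container
#'
#' Holds the sampled receive signals of one plane-wave firing as an
#' elements x samples matrix plus the sampling metadata needed to interpret
#' them. `t0` is the time of sample 1 relative to the transmit firing.
#'
#' @param samples Numeric matrix, one row per receive element.
#' @param sample_rate Sample rate in Hz.
#' @param t0 Time of the first sample in seconds (default 0).
#' @param elements Integer indices of the array elements the rows belong to
#'   (default `1:nrow(samples)`); used by multiplexed acquisitions where a
#'   firing records only a subset of the aperture.
#' @param element_x Optional lateral element positions (m) carried along for
#'   self-contained file round-trips.
#' @param sound_speed Optional medium sound speed (m/s) metadata.
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(samples, sample_rate, t0 = 0,
                     elements = seq_len(nrow(samples)),
                     element_x = NULL, sound_speed = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("`samples` must be a finite numeric matrix", call. = FALSE)
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("`sample_rate` must be > 0", call. = FALSE)
  if (length(elements) != nrow(samples))
    stop("`elements` must index every row of `samples`", call. = FALSE)
  structure(
    list(samples = samples, sample_rate = sample_rate, t0 = t0,
         elements = as.integer(elements),
         element_x = element_x, sound_speed = sound_speed),
    class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d element(s) x %d samples @ %.3g MS/s, t0 = %g us\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate / 1e6,
              x$t0 * 1e6))
  invisible(x)
}

#' @export
print.transducer_array <- function(x, ...) {
  cat(sprintf(
    "<transducer_array> %d elements, %.0f um pitch, %.2f MHz, %.0f%% BW(-6dB)\n",
    x$n_elements, x$pitch * 1e6, x$center_frequency / 1e6,
    100 * x$fractional_bandwidth_6db))
  invisible(x)
}

#' Multiplexer channel-to-channel crosstalk specification
#'
#' @param adjacent_db Power coupling to the nearest-neighbour channel in dB
#'   (<= 0); `-Inf` for none.
#' @param distant_db Coupling to all non-adjacent channels in dB; must not
#'   exceed `adjacent_db`.
#' @return An object of class `crosstalk_spec`.
#' @examples
#' crosstalk_spec(-45, -60)   # measured TFT multiplexer levels
#' @export
crosstalk_spec <- function(adjacent_db = -45, distant_db = -60) {
  if (adjacent_db > 0 || distant_db > 0)
    stop("crosstalk levels must be expressed as dB <= 0", call. = FALSE)
  if (distant_db > adjacent_db)
    stop("`distant_db` must be <= `adjacent_db`", call. = FALSE)
  structure(list(adjacent_db = adjacent_db, distant_db = distant_db),
            class = "crosstalk_spec")
}
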