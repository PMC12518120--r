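# Closed-form electrical and system-budget models: tissue attenuation and
# TGC, the TFT-switch RC front end, the Butterworth-Van Dyke source, the
# duty-cycled dual-noise-mode amplifier, and acquisition data/frame/depth
# budgets.

#' Frequency-dependent propagation attenuation
#'
#' `coefficient * frequency * depth`, doubled for round-trip propagation.
#' Soft tissue is typically 0.7 dB/(MHz*cm): a 7.5 MHz pulse making the
#' round trip to 4 cm loses 42 dB.
#'
#' @param frequency_mhz Frequency in MHz.
#' @param depth_cm One-way depth in cm.
#' @param coefficient_db_mhz_cm Attenuation coefficient in dB/(MHz*cm)
#'   (default 0.7).
#' @param round_trip Double for the two-way path (default TRUE).
#' @return Attenuation in dB.
#' @export
tissue_attenuation_db <- function(frequency_mhz, depth_cm,
                                  coefficient_db_mhz_cm = 0.7,
                                  round_trip = TRUE) {
  if (any(frequency_mhz < 0) || any(depth_cm < 0) ||
      any(coefficient_db_mhz_cm < 0))
    stop("attenuation arguments must be non-negative", call. = FALSE)
  coefficient_db_mhz_cm * frequency_mhz * depth_cm * if (round_trip) 2 else 1
}

#' Stepped time-gain-compensation schedule
#'
#' The receive gain that offsets depth-dependent attenuation, quantized to
#' `n_steps` uniformly spaced dB levels as a stepped-resistor
#' transimpedance stage realizes it. At time `t` after firing the echo
#' comes from depth `c t / 2`; the ideal gain is the round-trip
#' attenuation at that depth, and the applied gain is the largest step
#' level not exceeding it, hence monotone non-decreasing and never above
#' the ideal curve. The residual dynamic range left for later stages is at
#' most one step, `max_attenuation / (n_steps - 1)` dB (0 residual needs
#' `n_steps -> Inf`; `n_steps = 1` gives a constant 0 dB gain).
#'
#' @param t_acquisition Receive window in seconds.
#' @param sound_speed Sound speed (m/s).
#' @param frequency_mhz Centre frequency (MHz).
#' @param coefficient_db_mhz_cm Attenuation coefficient.
#' @param n_steps Number of gain levels (>= 1).
#' @param n_times Number of sampled time points of the returned curve.
#' @return Data frame with columns `time_s`, `depth_m`, `attenuation_db`
#'   (ideal continuous curve) and `gain_db` (stepped schedule).
#' @export
tgc_gain_schedule <- function(t_acquisition, sound_speed = 1480,
                              frequency_mhz = 7.5,
                              coefficient_db_mhz_cm = 0.7,
                              n_steps = 8L, n_times = 256L) {
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  t <- seq(0, t_acquisition, length.out = n_times)
  depth_m <- sound_speed * t / 2
  att <- tissue_attenuation_db(frequency_mhz, depth_m * 100,
                               coefficient_db_mhz_cm, round_trip = TRUE)
  if (n_steps == 1L) {
    gain <- rep(0, n_times)
  } else {
    step <- max(att) / (n_steps - 1)
    gain <- step * floor(att / step)
    gain <- pmin(gain, max(att))
  }
  data.frame(time_s = t, depth_m = depth_m, attenuation_db = att,
             gain_db = gain)
}

#' RC low-pass cutoff of the switch/parasitic front end
#'
#' The on-resistance of the multiplexer switch and the parasitic
#' capacitance ahead of the virtual ground form a first-order low-pass;
#' keeping the cutoff above 16 MHz with 5 pF of parasitics requires the
#' switch to stay below about 2 kOhm.
#'
#' @param r Resistance in ohms.
#' @param c Capacitance in farads.
#' @return Cutoff frequency `1 / (2 pi r c)` in Hz.
#' @export
rc_cutoff_hz <- function(r, c) {
  if (any(r <= 0) || any(c <= 0))
    stop("`r` and `c` must be > 0", call. = FALSE)
  1 / (2 * pi * r * c)
}

#' Fractional signal attenuation of a first-order RC low-pass
#'
#' `1 - 1 / sqrt(1 + (f / fc)^2)`: the fraction of amplitude lost at
#' frequency `f` relative to DC. At the 11.4 MHz transducer band edge a
#' 2 kOhm / 5 pF front end loses just under 19 %.
#'
#' @param f Frequency in Hz.
#' @param r,c Resistance (ohm) and capacitance (F).
#' @return Attenuation fraction in [0, 1).
#' @export
rc_attenuation_fraction <- function(f, r, c) {
  if (any(f < 0)) stop("`f` must be >= 0", call. = FALSE)
  fc <- rc_cutoff_hz(r, c)
  1 - 1 / sqrt(1 + (f / fc)^2)
}

#' Electrical front-end model parameters
#'
#' Butterworth-Van Dyke receiver source (series R1-L1-C1 motional branch
#' in parallel with the static capacitance C0) plus the TFT switch
#' resistance and the parasitic capacitances on either side of it.
#' Defaults: C0 = 100 fF, pre-switch parasitic C_p = 5 pF (two-tier foil
#' integration), R_TFT = 2 kOhm; L1/C1 resonate at 8.2 MHz.
#'
#' @param r_tft Switch on-resistance (ohm).
#' @param c_p Parasitic capacitance before the switch (F).
#' @param c_in Parasitic capacitance after the switch (F).
#' @param c0 Static transducer capacitance (F).
#' @param bvd_r1 Motional resistance (ohm).
#' @param bvd_l1 Motional inductance (H); default resonates `bvd_c1` at
#'   8.2 MHz.
#' @param bvd_c1 Motional capacitance (F).
#' @return Object of class `front_end_model`.
#' @export
front_end_model <- function(r_tft = 2e3, c_p = 5e-12, c_in = 1e-12,
                            c0 = 100e-15, bvd_r1 = 1e3,
                            bvd_c1 = 10e-12,
                            bvd_l1 = 1 / ((2 * pi * 8.2e6)^2 * bvd_c1)) {
  vals <- c(r_tft, c_p, c_in, c0, bvd_r1, bvd_l1, bvd_c1)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all front-end parameters must be positive", call. = FALSE)
  structure(list(r_tft = r_tft, c_p = c_p, c_in = c_in, c0 = c0,
                 bvd_r1 = bvd_r1, bvd_l1 = bvd_l1, bvd_c1 = bvd_c1),
            class = "front_end_model")
}

#' Butterworth-Van Dyke source impedance
#'
#' Series R1-L1-C1 motional branch in parallel with the static
#' capacitance C0. At the series resonance
#' `f = 1 / (2 pi sqrt(L1 C1))` the motional branch is purely real (R1);
#' towards DC the impedance grows as that of the capacitances (~1/f).
#'
#' @param f Frequency in Hz (> 0), vectorized.
#' @param model A [front_end_model()].
#' @return Complex impedance in ohms.
#' @export
bvd_impedance <- function(f, model) {
  stopifnot(inherits(model, "front_end_model"))
  if (any(f <= 0)) stop("`f` must be > 0", call. = FALSE)
  w <- 2 * pi * f
  z_series <- model$bvd_r1 + 1i * w * model$bvd_l1 +
    1 / (1i * w * model$bvd_c1)
  z_c0 <- 1 / (1i * w * model$c0)
  z_series * z_c0 / (z_series + z_c0)
}

#' Dual noise-mode amplifier model
#'
#' The low-noise (high-power) mode is engaged only while weak deep echoes
#' are expected; the amplifier otherwise runs at `1/power_ratio` of the
#' low-noise power. `static_overhead_fraction` is the fraction of the
#' low-noise power that cannot be duty-cycled.
#'
#' @param power_ratio_low_to_high_noise Low-noise-to-economy power ratio
#'   (default 4).
#' @param duty_low_noise Fraction of the receive window in low-noise mode
#'   (default 0.2).
#' @param static_overhead_fraction Non-switchable power fraction
#'   (default 0).
#' @return Object of class `noise_mode_model`.
#' @export
noise_mode_model <- function(power_ratio_low_to_high_noise = 4,
                             duty_low_noise = 0.2,
                             static_overhead_fraction = 0) {
  if (power_ratio_low_to_high_noise < 1)
    stop("power ratio must be >= 1", call. = FALSE)
  if (duty_low_noise < 0 || duty_low_noise > 1 ||
      static_overhead_fraction < 0 || static_overhead_fraction > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  structure(list(power_ratio_low_to_high_noise = power_ratio_low_to_high_noise,
                 duty_low_noise = duty_low_noise,
                 static_overhead_fraction = static_overhead_fraction),
            class = "noise_mode_model")
}

#' Amplifier power reduction from noise-mode duty cycling
#'
#' Ratio of always-low-noise power to duty-cycled power:
#' `1 / (o + (1 - o) * (d + (1 - d) / r))` with duty `d`, power ratio `r`
#' and static overhead `o`. The ideal defaults (r = 4, d = 0.2, o = 0)
#' give 2.5x.
#'
#' @param model A [noise_mode_model()].
#' @return Dimensionless power-reduction ratio (>= 1).
#' @export
tia_power_reduction <- function(model = noise_mode_model()) {
  stopifnot(inherits(model, "noise_mode_model"))
  o <- model$static_overhead_fraction
  d <- model$duty_low_noise
  r <- model$power_ratio_low_to_high_noise
  1 / (o + (1 - o) * (d + (1 - d) / r))
}

#' System acquisition budget parameters
#'
#' @param n_elements_total Total transducer elements (e.g. 1.5e5 for a
#'   50 cm^2 patch at 180 um pitch).
#' @param adc_bits ADC resolution in bits.
#' @param sample_rate ADC sample rate (Hz).
#' @param t_acquisition Receive window per firing (s).
#' @param n_angles Plane-wave compounding angles per frame.
#' @param frames_per_second Imaging frame rate (Hz).
#' @param sound_speed Sound speed (m/s).
#' @return Object of class `system_budget`.
#' @export
system_budget <- function(n_elements_total = 1.5e5, adc_bits = 10L,
                          sample_rate = 32e6, t_acquisition = 250e-6,
                          n_angles = 10L, frames_per_second = 50,
                          sound_speed = 1480) {
  vals <- c(n_elements_total, adc_bits, sample_rate, t_acquisition,
            n_angles, frames_per_second, sound_speed)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all budget fields must be positive", call. = FALSE)
  structure(list(n_elements_total = n_elements_total,
                 adc_bits = as.integer(adc_bits), sample_rate = sample_rate,
                 t_acquisition = t_acquisition, n_angles = as.integer(n_angles),
                 frames_per_second = frames_per_second,
                 sound_speed = sound_speed),
            class = "system_budget")
}

#' Compounded frame rate
#' @param t_acquisition Receive window per firing (s).
#' @param n_angles Compounding angles per frame.
#' @return `1 / (t_acquisition * n_angles)` in Hz (250 us x 10 angles
#'   gives 400 fps).
#' @export
frame_rate_hz <- function(t_acquisition, n_angles) {
  if (t_acquisition <= 0 || n_angles <= 0)
    stop("inputs must be > 0", call. = FALSE)
  1 / (t_acquisition * n_angles)
}

#' Imaging depth reachable in an acquisition window
#' @param t_acquisition Receive window (s).
#' @param sound_speed Sound speed (m/s).
#' @return `sound_speed * t_acquisition / 2` in metres (250 us in water
#'   reaches 18.5 cm).
#' @export
imaging_depth_m <- function(t_acquisition, sound_speed = 1480) {
  if (t_acquisition < 0 || sound_speed <= 0)
    stop("invalid inputs", call. = FALSE)
  sound_speed * t_acquisition / 2
}

#' Instantaneous acquisition data rate
#' @param budget A [system_budget()].
#' @return `n_elements_total * sample_rate * adc_bits` in bits/s
#'   (48 Tb/s for 1.5e5 elements, 10 b, 32 MS/s).
#' @export
data_rate_instantaneous_bps <- function(budget = system_budget()) {
  stopifnot(inherits(budget, "system_budget"))
  budget$n_elements_total * budget$sample_rate * budget$adc_bits
}

#' Average buffered data throughput
#'
#' `n_elements_total * (t_acquisition * sample_rate) * adc_bits *
#' frames_per_second`: the sustained rate when each frame's samples are
#' buffered on the patch and streamed out between firings.
#'
#' @param budget A [system_budget()].
#' @return Bits per second.
#' @export
data_rate_average_bps <- function(budget = system_budget()) {
  stopifnot(inherits(budget, "system_budget"))
  budget$n_elements_total * budget$t_acquisition * budget$sample_rate *
    budget$adc_bits * budget$frames_per_second
}

#' Multiplexing trade-off
#'
#' An `m`:1 receive multiplexer divides the silicon front-end and
#' interconnect count by `m` but requires `m` transmit firings to cover
#' the aperture, multiplying transmit energy per frame by the same factor.
#'
#' @param mux_ratio Inputs per multiplexer (>= 1).
#' @return List with `interconnect_reduction` and `tx_energy_factor`,
#'   both equal to `mux_ratio`.
#' @export
mux_tradeoff <- function(mux_ratio) {
  if (mux_ratio < 1) stop("`mux_ratio` must be >= 1", call. = FALSE)
  list(interconnect_reduction = mux_ratio, tx_energy_factor = mux_ratio)
}

#' Upper -6 dB band edge of a transducer
#' @param center Centre frequency (Hz).
#' @param fractional_bandwidth Fractional -6 dB bandwidth in (0, 2).
#' @return `center * (1 + fractional_bandwidth / 2)` (8.2 MHz at 78 %
#'   gives ~11.4 MHz).
#' @export
band_edge_hz <- function(center, fractional_bandwidth) {
  if (center <= 0 || fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    stop("invalid inputs", call. = FALSE)
  center * (1 + fractional_bandwidth / 2)
}

#' Closed-form system report
#'
#' Evaluates every budget/front-end closed form for one configuration;
#' the `budget` CLI subcommand serializes this to JSON.
#'
#' @param budget A [system_budget()].
#' @param fe A [front_end_model()].
#' @param nm A [noise_mode_model()].
#' @param mux_ratio Multiplexer ratio.
#' @param compressed_bits Bits/sample of the compressed encoding.
#' @return Named list of scalar quantities.
#' @export
system_report <- function(budget = system_budget(),
                          fe = front_end_model(),
                          nm = noise_mode_model(),
                          mux_ratio = 8, compressed_bits = 2) {
  tr <- mux_tradeoff(mux_ratio)
  list(
    instantaneous_data_rate_bps = data_rate_instantaneous_bps(budget),
    average_data_rate_bps = data_rate_average_bps(budget),
    frame_rate_hz = frame_rate_hz(budget$t_acquisition, budget$n_angles),
    imaging_depth_m = imaging_depth_m(budget$t_acquisition,
                                      budget$sound_speed),
    compression_ratio = compression_ratio(budget$adc_bits, compressed_bits),
    rc_cutoff_hz = rc_cutoff_hz(fe$r_tft, fe$c_p),
    rc_attenuation_at_band_edge = rc_attenuation_fraction(
      band_edge_hz(8.2e6, 0.78), fe$r_tft, fe$c_p),
    tia_power_reduction = tia_power_reduction(nm),
    interconnect_reduction = tr$interconnect_reduction,
    tx_energy_factor = tr$tx_energy_factor,
    round_trip_attenuation_4cm_db = tissue_attenuation_db(7.5, 4))
}
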