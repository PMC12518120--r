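---
title: "Log-delta RF compression for plane-wave B-mode imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-delta RF compression for plane-wave B-mode imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uspatch)
```

`uspatch` models the receive chain of a multiplexed wearable ultrasound
patch: plane-wave insonification of point/wire phantoms, per-element RF
digitization with a 2-bit log-delta codec, and offline B-mode
reconstruction with quantitative image-fidelity evaluation. This
vignette is the package's own account of those models — the assumptions
they make, the parameters that matter, the numerical choices taken where
several were defensible, and what the synthetic studies can and cannot
demonstrate.

## 1. The acquisition model

### Geometry and delays

A single unfocused plane wave at normal incidence travels straight into
the medium; a scatterer at lateral position $x_s$ and depth $z_s$ is
reached after $z_s/c$, and its echo returns to the element at $x_e$ over
the direct path $r = \sqrt{(x_s - x_e)^2 + z_s^2}$. The two-way delay is
therefore

$$\tau = \frac{z_s + r}{c}.$$

Steered transmissions are not modelled: the system under study transmits
one normal-incidence wave per firing, and compounding enters only
through the frame-rate budget. Coordinates are lateral $x$ (array
centred on 0) and depth $z > 0$; times are seconds from the transmit
firing; sample 1 of a frame is at `t0` (default 0).

### The pulse

The transmit excitation is a 5-cycle, 132 ns-period train, but the
waveform a receive channel actually records is shaped by the
transducer's passband, which is known (78 % fractional bandwidth at
−6 dB around 8.2 MHz) while the full electro-acoustic transfer is not.
The echo pulse is therefore modelled as a Gaussian-enveloped sinusoid at
$f_0 = 1/T_\mathrm{tx} \approx 7.58$ MHz whose envelope standard
deviation is set so the −6 dB points of the pulse spectrum sit at
$f_0(1 \pm \mathrm{BW}/2)$:

$$\sigma_f = \frac{\mathrm{BW} \cdot f_0}{2\sqrt{2\ln 2}}, \qquad
  \sigma_t = \frac{1}{2\pi\sigma_f}.$$

At the default bandwidth the Gaussian has decayed essentially to zero at
the gate edges ($\pm 330$ ns $\approx \pm 5\sigma_t$), so the gating is
cosmetic. Internally the simulator evaluates the pulse in continuous
time with its envelope peak at the arrival delay $\tau$, which makes the
envelope-detected image peak exactly at the scatterer depth and avoids
resampling error; `excitation_pulse()` exposes the sampled, causal,
zero-mean version (peak amplitude 1).

### Amplitudes, noise, artifacts

Each scatterer contributes amplitude

$$a = \rho \cdot \frac{1}{r^k} \cdot 10^{-\alpha f_0 (2 z_s) / 20},$$

with reflectivity $\rho$, receive spreading exponent $k$ (default 1 —
only "reflection and spreading losses" are known to exist, so the
exponent is configurable), and frequency-dependent attenuation
coefficient $\alpha$ in dB/(MHz·cm) evaluated at the centre frequency
(0 for the water-tank scenes; 0.7 is the typical soft-tissue value used
by the budget models). Receiver noise is white Gaussian, calibrated so
that the ratio of the **peak signal amplitude** to the noise standard
deviation equals `noise_snr_db`; the default 40 dB matches the
peak-over-background figure the wire-phantom image is expected to show.
Noise statistics beyond that are not specified by the system under
study, so white Gaussian is the assumption of least structure.

An optional saturated burst during the transmit window
(`tx_artifact_amplitude`) reproduces the electrical transmit-to-readout
coupling visible in real transients; `reconstruct_bmode(...,
blank_interval_s=)` excludes it from imaging. It is off by default
because the wires of interest arrive long after the transmit window.

### Multiplexing and crosstalk

With `mux_ratio`:1 multiplexers ahead of `n_frontends` front-ends, one
element per multiplexer is read per firing; `mux_acquisition()` returns
the resulting `mux_ratio` firings. The selection convention is: firing
$k$ (1-based) selects element $k + \mathrm{ratio}\cdot(m-1)$ for
front-end $m$ — each front-end owns a contiguous element block. The
firings partition the aperture exactly, and beamforming a schedule of
noiseless firings reproduces the full-aperture image bit-for-bit (a
tested property). Channel crosstalk is additive with amplitude coupling
$10^{\mathrm{dB}/20}$: one level for the two nearest neighbours
(−45 dB default) and one for all other channels (−60 dB), the measured
multiplexer levels.

## 2. The 2-bit log-delta codec

The codec state is an integer exponent $Y$ on a grid of
$n_\mathrm{levels}$ magnitudes $b^y$, $y \in [y_\mathrm{max} -
n_\mathrm{levels} + 1,\, y_\mathrm{max}]$. Defaults: 11 levels per
polarity, base $b = 2$, $y_\mathrm{max} = 0$ — i.e. 22 signed codes
spanning $20\log_{10} 2^{10} \approx 60$ dB, consistent with the
dynamic range assumed for the stages behind the front end. The base is
fixed to 2 by the decoder's power-of-two reconstruction but exposed as a
parameter for experimentation.

Per sample the encoder emits a **sign bit** ($x \ge 0$; exact zero
counts as positive — a documented convention, zeros carry no phase) and
a **delta bit**: strict comparison $|x[i]| > b^{Y}$ steps up, otherwise
down, one step per sample, clamped to the grid. The strict `>` yields
the expected toggle between the two nearest levels on a constant input.
A clamped step still emits the attempted direction, so the decoder —
which replays the recursion and outputs $D[i] = \mathrm{sign}[i]\cdot
b^{Y[i]}$ — stays in bit-exact lockstep with the encoder under all
inputs. The hardware's three-comparison sample loop is not modelled
gate-for-gate; the level recursion is the behavioural contract.

The initial level defaults to the grid minimum (a quiet start; the
converter's reset state is otherwise unspecified) and is configurable.
Serialization packs delta-then-sign per sample, MSB-first within bytes:
exactly 2 bits/sample, with grid parameters, initial level and the
normalization offset/scale in a JSON sidecar.

Two reference quantizers frame the codec. `quantize_linear()` rounds to
$n$ equispaced values on $[0,1]$ (half-step worst-case error).
`quantize_log_memoryless()` maps each sample to the nearest grid level
*in the log domain* — a magnitude at the geometric midpoint of two
levels rounds to the upper one (documented tie rule; linear-domain
rounding was the alternative and would bias small) — with no slew
constraint: it is the idealized many-comparator log ADC used in
level-count sweeps. `delta_stats()` quantifies why log spacing matters:
its `bits_required` is $\lceil \log_2 d_\mathrm{max}\rceil$ of the
largest jump between consecutive codes, defined as 1 for constant or
unit-step sequences. This unsigned convention reproduces the 60-codes →
6-bit arithmetic of direct delta coding on 10-bit data; a sign-inclusive
convention would give 7 bits and is deliberately not used.

Signals are normalized before encoding symmetrically around the mean
(`normalize_rf()`): subtract the mean, scale the largest absolute
deviation to the top of the grid. A whole frame is normalized jointly —
one full-scale for all channels, as a shared front-end reference
imposes — and the transform is returned for exact inversion.

## 3. Reconstruction

The offline chain mirrors standard plane-wave processing:

1. **Band-pass**: zero-phase frequency-domain Gaussian, unity gain at
   8 MHz, −6 dB at $\pm 25\%$ ("50 % bandwidth" is read as −6 dB
   fractional bandwidth, the ultrasound convention).
2. **Delay-and-sum**: pixel $(x, z)$ sums element samples at delay
   $(z + \sqrt{(x-x_e)^2 + z^2})/c$ with linear interpolation between
   samples (sub-sample delay error is bounded by the second derivative
   of the RF over one sample interval, negligible at 4× carrier
   sampling); no apodization (the system applies none); delays outside
   the record contribute zero.
3. **Envelope**: magnitude of the analytic signal along depth (FFT
   Hilbert transform).
4. **Log compression**: $20\log_{10}(v/\max v)$, clipped at
   −`dynamic_range_db` (30 dB for display, matching the wire-phantom
   presentation).

The default grid places lateral pixels at the element positions and
axial pixels at $c/(2 f_s)$ — one pixel per RF sample of round-trip
travel, 23.1 µm in water at 32 MS/s. Averaging of repeated firings
(10 by default, as the system acquires) is the sample-wise mean and
precedes filtering.

## 4. Fidelity evaluation

SSIM uses **global image moments** with no windowing and no stabilizing
constants:

$$\mathrm{SSIM} = \frac{2\mu_x\mu_y \cdot 2\sigma_{xy}}
  {(\mu_x^2 + \mu_y^2)(\sigma_x^2 + \sigma_y^2)},$$

the form the evaluation is defined with. A guard $\varepsilon =
10^{-12}$ enters a denominator factor only when both of its terms are
below $\varepsilon$, so constant-image degeneracies stay finite without
perturbing ordinary inputs. The value is invariant to
population-vs-sample moment normalization (both $\sigma$ terms rescale
identically); the tests exploit this by checking against an independent
sample-moment implementation. Windowed SSIM was considered and not
adopted: the printed definition has no window, and global moments are
what the acceptance comparisons use.

Compared images are the final log-compressed B-mode images mapped to
$[0,1]$ over a fixed 60 dB span (`bmode_unit_image()`). The comparison
domain is a genuine open choice — raw RF, envelope, or display image
would all be defensible — and the display image over the full 60 dB
codec range was chosen because image similarity is the quantity the
compression claim is about.

`quant_sweep()` evaluates a strategy at a level count by quantizing
**each firing individually** (each acquisition passes through its own
converter), averaging the decoded firings, reconstructing, and computing
SSIM against the float-RF reconstruction of the same averaged firings.
Running the codec inside the averaging loop is not an embellishment: it
is where the converter sits in the physical chain, and the noise-dithered
averaging it implies is part of why the 2-bit stream preserves the
image.

## 5. The synthetic study and its scope

The standard study scene (`default_run_config()`, `run_simulation()`)
is: three unit-reflectivity wires at 34/37/40 mm on axis in water
(c = 1480 m/s, attenuation 0), plus 150 diffuse scatterers of mean
reflectivity 0.03 spread uniformly over the 30–43 mm imaging window to
emulate a weak speckle background; 32 elements, 2048 samples at
32 MS/s, 10 firings at 40 dB peak SNR, averaged. Reconstruction covers
30–43 mm at the default grid (563 × 32 pixels — the scale at which all
shipped studies run; one full study takes a few seconds on one core).
Wire depths generally fall between axial pixels, so "within one pixel"
statements are measured from the grid point nearest the true depth.

What the generator emulates: geometric plane-wave delays, band-limited
pulses, spreading and attenuation losses, additive receiver noise,
multiplexed acquisition, channel crosstalk, transmit coupling. What it
does not: fully developed speckle from sub-resolution scatterer
densities, element directivity, multiple scattering, phase aberration,
motion, and the anatomical amplitude statistics of clinical RF data.
Passing the synthetic SSIM thresholds therefore shows that the codec
preserves point-target imaging and a weak diffuse background under the
modelled physics — it is a desk-scale substitute for, not a reproduction
of, fidelity curves measured on clinical recordings, whose richer
amplitude statistics the generator does not claim to match.

## 6. Degenerate inputs and error handling

Constant signals cannot be normalized (nothing to encode) and all-zero
envelope images cannot be log-compressed: both are rejected with
explicit errors. Scatterers arriving after the recorded window warn and
are dropped. Firing schedules that do not cover the aperture exactly are
rejected at beamforming. The RF HDF5 container validates its required
attributes on read and names the missing field. Empty sweeps return
empty, well-typed results.

## 7. Known limitations

* The codec model is behavioural: comparator offsets, settling and
  glitch dynamics of a physical converter are out of scope.
* The electrical front-end models are first-order closed forms intended
  for budget reasoning, not circuit simulation; the duty-cycled
  amplifier model exposes a static-overhead parameter precisely because
  real implementations fall short of the ideal ratio.
* The average-throughput closed form
  (elements × samples/frame × bits × fps) is reported as computed;
  at the default patch parameters it evaluates to 6 × 10^11 b/s.
* Plane-wave transmission is normal-incidence only; steering and
  compounding beyond the rate budget are future extensions.
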