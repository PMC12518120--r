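# uspatch

Plane-wave ultrasound simulation, 2-bit log-delta RF compression and
B-mode reconstruction in R.

## The problem

Wearable ultrasound patches need very large transducer counts (order
10^5 elements for a patch of tens of cm^2 at 180 µm pitch), and raw RF
digitization at that scale is untenable: 1.5 × 10^5 elements sampled at
32 MS/s with 10-bit ADCs would produce an instantaneous data rate of
48 Tb/s. Two architectural levers make a patch feasible:

* **receive multiplexing** — an *m*:1 switch in front of each silicon
  front-end divides the interconnect and front-end count by *m*, at the
  cost of *m* transmit firings per frame; and
* **on-element data compression** — encoding each RF sample with 2 bits
  instead of 10 cuts the transmitted volume five-fold.

`uspatch` is a tool for studying the second lever quantitatively. It
implements the whole chain — synthetic plane-wave RF acquisition,
quantization/encoding, B-mode reconstruction, image-fidelity metrics —
plus the closed-form electrical and budget models used to reason about
the front end. All experiments run on synthetic wire/point phantoms
generated by the package itself; no external data are required.

## The codec

RF samples are tracked on a logarithmic amplitude grid of 11 levels per
polarity (22 signed codes, base 2, a 60 dB magnitude range). Per sample
the encoder emits exactly two bits:

* a **delta bit**: the tracked level exponent *Y* steps up when
  |x[i]| > 2^Y and down otherwise (one step per sample, clamped to the
  grid) — delta modulation in the log domain; and
* a **sign bit** capturing the RF phase, which beamforming needs.

The base station replays the recursion and reconstructs

    D[i] = sign[i] · 2^{Y[i]}

Because a logarithmic grid makes consecutive magnitudes differ by few
codes, one delta bit suffices where direct delta coding of 10-bit linear
codes would need 6 bits (jumps up to 60 codes out of 1024, only a 40 %
saving). Image quality is evaluated with the global-moment structural
similarity index

    SSIM = (2 μx μy · 2 σxy) / ((μx² + μy²)(σx² + σy²))

between the B-mode image reconstructed from compressed RF and the one
from full-precision RF.

## Worked example

Simulate the standard validation scene — three wires at 34/37/40 mm in
water plus weak diffuse scatterers, 32 elements at 180 µm pitch,
8.2 MHz / 78 % bandwidth, 32 MS/s, 10 averaged firings at 40 dB peak
SNR — then compare quantization strategies:

```r
library(uspatch)

cfg <- default_run_config()          # the system's parameter set, seed 1
sim <- run_simulation(cfg)

rbind(
  quant_sweep(sim$frames, "linear",    2^10, sim$array, sim$grid),
  quant_sweep(sim$frames, "log",       22L,  sim$array, sim$grid),
  quant_sweep(sim$frames, "log_delta", 22L,  sim$array, sim$grid))
#>   strategy levels      ssim
#>     linear   1024 0.9999922
#>        log     22 0.9989256
#>  log_delta     22 0.9717233
```

10-bit linear quantization is visually lossless (SSIM ≈ 1); 22
memoryless log codes already stay above 0.99; and the full 2-bit
log-delta codec — a 5× reduction versus 10-bit ADCs — keeps SSIM above
0.95. The wires are recovered where they were placed:

```r
bm <- reconstruct_bmode(sim$frame, sim$array, sim$grid,
                        dynamic_range_db = 30)
find_bright_maxima(bm, 3)
#>       x          z        db
#>  -9e-05 0.03400062  0.000000
#>   9e-05 0.03700688 -0.847976
#>   9e-05 0.03999000 -1.339511
```

The closed-form system report reproduces the budget arithmetic
(48 Tb/s instantaneous rate, 400 fps at 250 µs × 10 angles, 18.5 cm
depth in water, 5× compression, 2.5× front-end power saving from
noise-mode duty cycling):

```r
str(system_report()[1:5])
#> $ instantaneous_data_rate_bps: num 4.8e+13
#> $ average_data_rate_bps      : num 6e+11
#> $ frame_rate_hz              : num 400
#> $ imaging_depth_m            : num 0.185
#> $ compression_ratio          : num 5
```

A thin command-line wrapper over these functions lives in
`inst/cli/uspatch.R` (subcommands `simulate`, `encode`, `decode`,
`image`, `sweep`, `budget`); RF frames travel in a small documented HDF5
container, encoded bitstreams as packed 2-bit payloads with a JSON
sidecar.

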