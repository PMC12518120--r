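Package: uspatch
Title: Plane-Wave Ultrasound Simulation, Log-Delta RF Compression and
    B-Mode Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying RF data compression in wearable
    ultrasound patches. Simulates plane-wave acquisitions of point/wire
    phantoms on a multiplexed linear receive array, encodes the per-element
    RF signals with a 2-bit log-delta scheme (1-bit delta modulation over
    logarithmically spaced amplitude levels plus a sign bit), reconstructs
    B-mode images by delay-and-sum beamforming with Hilbert envelope
    detection and logarithmic compression, and evaluates image fidelity
    with a global-moment structural similarity index. Closed-form models
    of tissue attenuation, time-gain compensation, the transducer and
    thin-film-transistor multiplexer front end, and acquisition data-rate
    budgets are included, together with an HDF5 RF container and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    rhdf5,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
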