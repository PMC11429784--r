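Package: beatpilot
Title: Desk-Scale Simulation and Analysis of Beat Pilot Tone RF Motion Sensing in MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how radio-frequency tones transmitted into an MRI bore form
    standing waves (the bore treated as an air-filled circular waveguide), how
    receiver coils sample those waves as magnetic flux, and how second-order
    intermodulation in the receive chain places a motion-modulated beat tone
    inside the k-space receiver band. Provides the full extraction and analysis
    chain: per-readout tone extraction and notching, percent modulation,
    zero-group-delay filtering, pseudo-inverse phase estimation, accelerometer
    double integration to displacement, PCA-based motion separation, multicoil
    regression against reference motion traces, and multiple-antenna (MIMO)
    channel handling. Includes seeded synthetic-scenario generators (coil
    translation sweeps, coil vibration events, respiratory/cardiac physiology
    with a displacement-ballistocardiogram waveform, and a two-antenna head
    motion calibration/inference pair) so every pipeline runs end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    signal,
    pracma,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
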