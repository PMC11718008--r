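Package: fmcwvitals
Title: Non-Contact Cardiorespiratory Monitoring with Seat-Back FMCW Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and processes frequency-modulated continuous-wave
    (FMCW) radar recordings of a seated person to recover breathing rate,
    heart rate, and heart-rate variability without body contact. Provides a
    forward model that synthesizes raw beat-signal data cubes from
    parametric breathing, cardiac, and body-movement displacement, and the
    full inverse chain: chirp averaging, range FFT, multi-bin phase
    extraction and unwrapping, time-domain body-movement compensation,
    breathing-band estimation, variational mode decomposition of the
    cardiac band, breathing-harmonic rejection, cardiac waveform
    reconstruction from at least two harmonics, valley-based interbeat
    intervals, RMSSD/SDRR/pNN50, and waveform-morphology flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
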