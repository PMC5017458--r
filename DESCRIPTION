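Package: respvmd
Title: Multi-Target Respiration Tracking from Ultra-Wideband Impulse
    Radar via Variational Mode Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Non-contact monitoring of several people breathing at the
    same distance from a single-channel ultra-wideband (UWB) impulse
    radar.  Simulates slow-time by fast-time radar echo matrices from
    multiple breathing targets (sinusoidal chest displacement modulating
    the delay of a first-derivative Gaussian pulse, plus static clutter
    and white noise), selects the motion-bearing range bin by slow-time
    variance, separates per-target respiration waveforms with a
    variational mode decomposition (VMD) solver written from scratch
    (alternating Wiener-filter mode updates, power-centroid center
    frequencies, dual ascent), and tracks each target's time-varying
    respiration rate through Hilbert-transform instantaneous frequency
    with rectangular-window smoothing and low-amplitude gating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
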