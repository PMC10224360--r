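Package: electrome
Title: Band-Power and Time-Dispersion Analysis of Plant Electrophysiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing electrophytogram (EPG) recordings: micro-voltage
    time series sampled from plant tissue. Provides a synthetic electrome
    generator with controllable 1/f^beta background and band-limited oscillatory
    components, Welch power spectral density estimation, average band power over
    neuroscience-style frequency bands by composite Simpson integration,
    per-minute signal features (spectral centroid mean frequency, mean potential
    difference), and time dispersion analysis of features (TDAF) across
    replicate plants with before/after phase comparison. All user-facing
    functions take and return tidy data frames; results carry broom-style
    tidy()/glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
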