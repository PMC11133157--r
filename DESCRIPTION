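Package: pupilverse
Title: Multiverse Analysis of Infant Pupillometry Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for specification-curve (multiverse) analysis of
    event-locked pupillometry recordings. Five forking preprocessing
    operators (extreme-value trimming, area-of-interest gaze filtering,
    blink exclusion versus linear interpolation, subtractive baseline
    correction at three window lengths, and missingness-based participant
    exclusion) expand one binocular 60 Hz recording into a lattice of 48
    plausible datasets. Two competing penalized-spline regression models
    (a time-varying condition model and a mean-effect model) are fitted to
    every dataset and compared by BIC and adjusted R-squared; results are
    summarized as a 96-estimate specification curve and a condition
    difference smooth over trial time with significant windows. A seeded
    synthetic-session generator with known ground truth supports testing
    and calibration without access to raw eye-tracker data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
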