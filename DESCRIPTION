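Package: gpmoist
Title: Measurement and Closed-Loop Control of Germination Paper Water Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and control toolkit for gravimetric water
    content of germination paper (GP) used as a growth substrate in plant
    phenotyping. Implements the capacitor-discharge resistance measurement
    channel with logarithmic calibration curves and a banded heteroscedastic
    noise model, a Penman-derived humidity-dependent evaporation model for GP
    sheets, a scalar Kalman filter combining the water-balance model with raw
    measurements, discrete PI and quantized-actuation model predictive
    irrigation controllers (individual and group modes), and a closed-loop
    experiment runner with control-quality metrics (maximal deviation,
    integral of squared error). All inputs are synthetic; generators for
    sheet cohorts, ambient humidity and calibration data are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
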