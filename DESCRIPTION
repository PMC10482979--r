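Package: thermadapt
Title: Thermal Adaptation of Soil Microbial Respiration from MMRT Temperature Response Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify thermal adaptation of soil microbial respiration from
    substrate-unlimited temperature response curves. Converts tube-level headspace CO2
    measurements from temperature-gradient-block incubations into glucose-induced
    respiration curves, fits macromolecular rate theory (MMRT) with a temperature-dependent
    activation heat capacity by non-linear least squares, extracts the temperature optimum
    (Topt) and inflection point (Tinf) of each curve, estimates the adaptation rate of these
    metrics against mean environmental soil temperature with spatial simultaneous
    autoregressive (SAR) error models, and projects over- or under-estimation of respiration
    under warming scenarios from a scaled thermal response surface. Includes a synthetic
    study generator so every pipeline stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    geosphere,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
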