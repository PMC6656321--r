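Package: ramresp
Title: Respirometry and Accelerometry Analysis for Free-Swimming Obligate Ram Ventilators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intermittent-flow respirometry of large,
    free-swimming fishes that must swim to ventilate. Converts raw oxygen-logger
    and 25-Hz triaxial accelerometer time series into quality-filtered,
    background-corrected oxygen consumption rates (MO2), maximum and minimum
    routine metabolic rate, aerobic scope, and critical oxygen limits
    (concentration, saturation and partial pressure) via a breakpoint
    regression against the minimum routine rate. Tailbeat frequency, tailbeat
    acceleration amplitude and overall dynamic body acceleration are extracted
    from acceleration with a 3-s static/dynamic split and an analytic Morlet
    continuous wavelet transform. Mixed-effects models with within-animal AR(1)
    correlation relate activity to metabolic rate, with BIC model selection,
    cluster-bootstrap prediction intervals and paired temperature contrasts.
    A trial simulator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nlme,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
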