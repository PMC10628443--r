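Package: droughtflux
Title: Gravimetric Analysis of Whole-Plant Water Relations in Drought
    Phenotyping Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing gravimetric (lysimeter-array) drought
    experiments on container-grown plants: extraction of transpiration
    rate, daily transpiration, volumetric soil water content and canopy
    conductance from raw system-weight time series; segmented
    (plateau-then-decline) regression of midday transpiration rate
    against soil water content with breakpoint, decline slope, terminal
    drought point and trapezoid water-use integral; relative
    transpiration, drought-recovery (resilience) rate, water-use
    efficiency and water-use behaviour classification; and a feedback
    deficit-irrigation experiment simulator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: grDevices, graphics, jsonlite, stats, tools, utils, yaml
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
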