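Package: bloomdyn
Title: Spatiotemporal Bloom Dynamics from Gridded Chlorophyll-a Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for harmful-algal-bloom indicators derived from
    satellite ocean-colour imagery of turbid inland waters. Converts two-band
    red/red-edge water-leaving reflectance to chlorophyll-a concentration,
    composites daily grids to a 14-day calendar, fills cloud gaps with a
    two-step spatial k-nearest-neighbour plus neighbour-year climatology
    procedure, characterises periodicity with a Morlet continuous wavelet
    transform including red-noise (AR(1)) significance testing, screens
    environmental covariates for multicollinearity with iterated variance
    inflation factors, and maps per-pixel seasonal variable importance with a
    from-scratch multivariate adaptive regression splines (MARS)
    implementation. A seeded synthetic-data generator emulates the statistical
    structure of a biweekly bloom-hotspot grid so the full pipeline is testable
    without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
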