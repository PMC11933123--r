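Package: tlrhm
Title: Two-Leaf Daily Gross Primary Productivity from a Temperature-Adapted
    Rectangular Hyperbola
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily canopy gross primary productivity (GPP) modelling for
    eddy-covariance flux sites. A coupled enzyme-kinetic (Farquhar-type)
    and Ball-Woodrow-Berry leaf photosynthesis model is compressed into
    rectangular-hyperbola parameter surfaces (quantum yield and maximum
    photosynthetic rate as functions of air temperature and Vcmax,25),
    integrated analytically over sine or squared-sine diurnal radiation,
    upscaled to the canopy with a sunlit/shaded two-leaf scheme, and
    downregulated by a vapour-pressure-deficit scalar. Includes ensemble-run
    calibration of Vcmax,25 against measured daily GPP, daily driver table
    input/output, and a seeded synthetic site-year generator with a
    half-hourly enzyme-kinetic truth oracle for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
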