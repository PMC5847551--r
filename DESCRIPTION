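Package: nightrange
Title: Artificial Light at Night Exposure Within Species Geographic Ranges
Version: 0.1.0
Authors@R: person("Night", "Range Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify artificial light at night (ALAN) within
    species geographic ranges from multi-year stacks of nighttime-light
    composites. Provides intercalibration of digital-number (DN) composites
    onto a common reference scale by median (L1) quadratic regression,
    rasterization of range polygons on an equal-area grid, per-species lit
    fractions and cumulative-brightness evenness, Mann-Kendall trend tests
    with tie correction, species-richness grids with brightness
    correlations, and a use/non-use group comparison on arcsine-square-root
    transformed proportions. Includes a synthetic nightscape and range
    generator with known ground truth so the full pipeline is testable
    without external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
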