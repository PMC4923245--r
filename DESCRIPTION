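Package: sbfsim
Title: Simulation and Models of Spatiotemporal Boundary Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying spatiotemporal boundary formation (SBF): the
    perception of illusory edges, shapes, and motion from sparse, sequential
    transformations of texture elements. Generates the minimal sawtooth
    element-transformation displays produced by a virtual moving bar,
    converts between physical bar parameters and display timing (SOA, ISI,
    EOD), recovers local illusory-edge orientation, speed, and bar width
    from transformation events under a temporal-integration gate, explores a
    motion-energy-filter account of edge recovery, and regenerates two
    psychophysics experiments (4AFC width matching plus illusory-strength
    ratings) with a parametric simulated observer.
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
    utils,
    withr,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
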