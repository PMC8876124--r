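Package: mycomech
Title: Compression Mechanics of Mycelium-Bound Composites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for uniaxial compression testing of
    mycelium-bound particle composites. Reduces load-displacement records to
    engineering stress-strain curves and foam-mechanics summary statistics
    (elastic modulus from a strain window anchored at 10 percent strain,
    compressive strength at 20 percent strain, mean curves with pointwise 95
    percent confidence bands). Identifies a compressible Neo-Hookean
    constitutive model from uniaxial data through its closed-form axial
    stress, verified against an independent energy-minimisation oracle.
    Simulates the compression test with total-Lagrangian hexahedral finite
    elements and rigid-stamp penalty contact on cylinder meshes with slanted
    top faces. Provides Feret-diameter shape statistics and sieve-fraction
    classification for substrate particles, and a seeded synthetic-study
    generator so the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
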