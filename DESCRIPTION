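Package: ecmech
Title: Mechanics and Imaging Quantification of Decellularized Lung
    Extracellular Matrix
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies atomic force microscopy (AFM) nanoindentation
    mechanics and fluorescence imaging readouts of decellularized lung
    extracellular matrix (ECM) probed at residual versus functional lung
    volume in young and aged animals. Fits the Hertz sphere contact model
    with cantilever-compliance correction and joint contact-point search,
    derives a hysteresis-based viscosity index and pull-off adhesion
    force, quantifies ECM protein immunofluorescence by kernel density
    estimation of pixel intensities, segments nuclei and scores Ki67
    proliferation and live/dead viability, and compares groups with
    two-sample t-tests and two-way (age x volume) factorial ANOVA.
    Ships a synthetic-data generator with known ground truth so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
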