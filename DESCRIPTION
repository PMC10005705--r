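Package: osteomech
Title: Bone Biomechanics, Viscoelasticity and MicroCT Morphometry for
    Rodent Osteoporosis Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantitative bone analysis in
    ovariectomized rodent studies: three-point-bending mechanics of tibial
    midshafts (offset yield detection, post-yield displacement, pop-in
    events, body-size normalization), dynamic mechanical analysis of
    sinusoidal stress/strain traces (storage modulus, loss modulus, loss
    tangent across a frequency sweep), calibrated micro-CT regional
    morphometry (phantom-based density calibration, block and sector BMD,
    BMC and BV/TV, cross-sectional diameter estimation), and exact
    small-sample nonparametric statistics (enumerated Mann-Whitney U,
    Kruskal-Wallis with post hoc pairs). A synthetic-data module generates
    every input with known ground truth - standard-linear-solid
    viscoelastic traces, elastoplastic bending curves with pop-ins, hollow
    tube voxel phantoms with hydroxyapatite calibration inserts, and
    longitudinal cohort tables - so every stage of the pipeline is
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
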