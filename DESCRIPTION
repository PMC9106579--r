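Package: granuleface
Title: Structural Correlation of Membraneless Organelles and Cytoskeletal
    Filaments in 3D Confocal Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies structural correlations between membraneless
    organelles (stress granules) and cytoskeletal filaments (microtubules)
    in multi-channel 3D confocal stacks of micropatterned cells. Implements
    ensemble reference-cell normalization, multi-threshold granule detection
    with a quality-factor sweep, radial and surface-relative distribution
    functions, bulk and surface partition coefficients, and a Pickering-type
    thermodynamic model of particle adsorption at diffuse droplet interfaces
    with a robust one-parameter fit. Includes a seeded synthetic-scene
    generator with ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
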