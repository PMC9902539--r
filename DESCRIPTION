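Package: lamellar
Title: Quantitative Analysis of Plasma-FIB Cryo-Lamellae and Depth-Dependent
    Particle Damage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative quality control of plasma focused-ion-beam
    (PFIB) milled cryo-lamellae and of subtomogram-averaging experiments run on
    them. Implements the sputter-volume geometry for milling-rate measurements
    at arbitrary incidence angles (tilt-corrected cuboid and parallelepiped
    volumes, through-origin rate fits, angular-dependence summaries),
    interpolation of manually digitised lamella boundary models into continuous
    top/bottom surfaces, per-particle distance-to-surface and local-thickness
    annotation, distance-shell partitioning with tomogram-matched control sets,
    Fourier shell correlation with threshold resolution, and
    Rosenthal-Henderson B-factor estimation. A synthetic-data module generates
    every input with known ground truth (lamella slabs with tilt and thickness
    gradients, particles, depth-dependent structure-factor attenuation, noisy
    milling measurements) so the full pipeline can be exercised and validated
    end to end. Reads and writes RELION-dialect STAR particle tables,
    plain-text boundary-point models, and MRC2014 volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
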