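Package: octaquant
Title: Quantification of En-Face OCT and OCTA Macular Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies en-face optical coherence tomography (OCT) and OCT
    angiography (OCTA) slabs of the macula: perfusion density, vessel length
    density and vessel diameter index of the retinal capillary plexuses inside
    a foveal circular region of interest, choriocapillaris perfusion density
    after Phansalkar local thresholding, and normalized ellipsoid-zone
    reflectivity against vitreous (dark) and retinal nerve fiber layer
    (bright) references. Includes paired study-vs-fellow-eye statistics
    (descriptives, Shapiro-Wilk normality, paired two-tailed t-tests, a
    noncentral-t power and sample-size calculation) and synthetic-data
    generators with known ground truth for vessel networks, choriocapillaris
    texture, reflectance scenes and paired-eye cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    EBImage,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
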