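Package: osteoquant
Title: Histomorphometric and Diffraction Quantification of Bone-Graft
    Biomaterials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification chain for evaluating bone-graft biomaterials in
    stained histological sections and by powder X-ray diffraction. Provides
    seeded generators for synthetic section phantoms with planted ground
    truth, three-class nearest-centroid color segmentation, histomorphometric
    area fractions and the bone-to-material-contact (BMC) osteoconductivity
    statistic on a pixel-edge perimeter metric, Voigt peak fitting with
    Scherrer crystallite-size estimation from the Lorentzian integral
    breadth, phase identification by d-spacing matching, random-intercept
    mixed-model group comparisons with Scheffe-adjusted pairwise tests, and
    a noncentral-F ANOVA sample-size calculation, composed into a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    png,
    jsonlite,
    yaml,
    lme4,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    tiff,
    mgcv,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
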