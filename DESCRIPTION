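Package: cordstereo
Title: Design-Based Stereological Morphometry of Spinal Cord Segments
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for design-based stereology of segmented organs, built
    around the workflow used for equine cervical spinal cord morphometry:
    systematic-uniform-random slab sampling, randomized point-counting
    grids on labeled cross-section images, point-count area estimation,
    Cavalieri volume estimation with Gundersen-Jensen coefficients of
    error, diameter and compression-ratio morphometry, shrinkage
    bookkeeping, and the segment-level statistical layer (mean and
    standard error, Duncan's multiple range test with compact letter
    display, Pearson correlation tables). Includes an analytic
    spinal-cord phantom generator with closed-form compartment areas and
    volumes for estimator validation, and machine-readable fixtures of
    the published summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
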