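Package: flimtex
Title: Texture Analysis of Fluorescence Lifetime Images of Red Blood Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free phenotyping of red blood cells from fluorescence
    lifetime imaging (FLIM) matrices. Provides first-order lifetime-histogram
    features, the rotation-invariant uniform Local Binary Pattern (riu2)
    texture transform with interpolated circular sampling, Fisher linear
    discriminant analysis with stepwise feature selection, leave-one-out and
    repeated hold-out validation at cell and patient level, nonparametric
    group comparisons, a bright-focus detector, and a synthetic FLIM-image
    generator that emulates control, non-sickled and sickled sickle-cell
    disease erythrocyte phenotypes so the whole pipeline can be exercised
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tiff,
    igraph,
    EBImage,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
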