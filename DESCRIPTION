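Package: ctcscope
Title: Enrichment-Free Circulating Tumour Cell Detection, Enumeration and
    Analytical Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open, testable re-implementation of an enrichment-free
    circulating tumour cell (CTC) detection workflow on immunofluorescent
    slides. Generates synthetic multi-channel (DAPI/CK/CD45/+1) slide tiles
    with known ground truth, segments every nucleated cell, extracts
    morphometric and intensity features, classifies cells into five CTC
    subtypes (traditional, small, cluster member, CK-negative, apoptotic)
    with an auditable rule base, enumerates CTCs per millilitre of blood,
    and implements the analytical-validation study designs and statistics
    (percent recovery, linearity, specificity, four-way precision as
    percent coefficient of variation). Downstream single-cell biomarker
    modules provide fourth-channel protein quantitation, two-colour FISH
    signal counting with PTEN/CEP10 deletion-status calling, and 100-kb
    windowed log2 copy-number profiles against a matched control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    png,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
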