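Package: nichetrace
Title: Spatial Niche Analysis of Premalignant Tissue at Single-Cell Resolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing imaging-based spatial transcriptomics of
    premalignant tissue: diffusion-map cell-state continua, radius-based
    multicellular niches ordered along an epithelial diffusion component,
    compartment-specific niche expression, ligand-receptor communication
    module discovery, transcriptome-based copy-number classification,
    point-pattern tissue morphometry, and spatially annotated
    differential-abundance neighbourhoods. Ships a synthetic-tissue
    generator with full ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RANN,
    igraph,
    jsonlite,
    EBImage,
    methods,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
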