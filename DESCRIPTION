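Package: fcss
Title: Flow Cytometric Seed Screen Analysis for Reproductive-Mode Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers plant reproductive modes (sexual reproduction,
    pseudogamous and autonomous gametophytic apomixis, BIII hybrids) from
    flow cytometric seed screen (FCSS) data. Provides a fertilization
    scenario calculus for expected embryo and endosperm C-values, automatic
    peak detection and embryo/endosperm role assignment on DNA-content
    histograms (including the endopolyploidy second-peak rule), internal
    standard genome-size estimation, gamete genome-size back-calculation
    for scenario selection, species-level summaries of facultative
    apomixis, and a permutation-based redundancy analysis (pseudo-F) for
    comparing trait syndromes of apomictic and sexual species. A synthetic
    data module simulates DAPI-stained seed histograms and species trait
    tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
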