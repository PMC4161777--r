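Package: ctcpheno
Title: Single-Cell Phenotyping of Circulating Tumour Cells in
    Immunofluorescence Cytospins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects cytokeratin-positive circulating tumour cells (CTCs)
    in multi-channel immunofluorescence cytospin images (DAPI,
    pan-cytokeratin, ALDH1, TWIST), classifies each cell by ALDH1
    expression level (high/low/negative, via exposure-time-equivalent
    cut-offs calibrated on labelled control cells) and by TWIST
    subcellular localization (nuclear/cytoplasmic/negative), assigns one
    of four co-expression phenotypes per CTC, and aggregates phenotype
    frequencies to patient and cohort level with early-versus-metastatic
    comparisons (chi-square with continuity correction, Mann-Whitney,
    Spearman). Ships a synthetic cytospin simulator with known ground
    truth so the whole pipeline is testable without imaging hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
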