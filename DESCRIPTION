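Package: methylegacy
Title: Transgenerational Sperm Methylome Analysis from RRBS Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tile-based differential methylation calling from reduced
    representation bisulfite sequencing (RRBS) count files, cross-generation
    conserved-site intersection, and a label-permutation test for inherited
    methylation change across a multi-generation breeding design. Includes a
    beta-binomial RRBS count simulator with known injected differentially
    methylated sites, genomic feature annotation with a redefined promoter
    window, and the closed-form reproductive endpoint formulas used in
    rodent multigeneration toxicology studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
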