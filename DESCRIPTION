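Package: neovax
Title: Personalized Neoantigen Vaccine Design and ctDNA Response Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for personalized neoantigen long-peptide
    vaccines in solid tumors: consensus filtering of tumor/normal somatic
    call-sets with RNA-level validation, neoantigen calling from externally
    predicted MHC binding affinities (median IC50 thresholding), tiered
    candidate prioritization, 27-mer long-peptide and dose-pool design with a
    prime-boost schedule, longitudinal circulating tumor DNA (ctDNA) panel
    monitoring with dynamic-pattern classification, IFN-gamma ELISpot
    response calling, and recurrence-free survival analysis with
    propensity-score matched controls. Includes a synthetic-cohort generator
    that emulates the statistical structure of such trials so every stage is
    testable without access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    methods,
    stats,
    utils,
    survival,
    vcfR,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    withr
Config/testthat/edition: 3
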