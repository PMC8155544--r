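Package: haystackr
Title: Candidate-Gene Prioritization and Assay Quantification for Severe
    Spermatogenic Failure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exome-based candidate-gene discovery for men with severe
    spermatogenic failure (Sertoli cell-only azoospermia). Implements a
    five-stage loss-of-function variant filtering cascade with a full
    per-stage audit trail (variant effect and population rarity, call
    quality, genotype-stratified allele-frequency cutoffs, testis-biased
    expression, and exclusion of genes hit in fertile controls), an
    allele-level loss-of-function burden test (exact conditional
    two-sided Fisher test with a Woolf logit confidence interval and
    Haldane-Anscombe correction), an inheritance-aware known-gene panel
    screen, calculators for CRISPR growth-competition allele-class
    dynamics and dye-dilution proliferation assays, and seeded synthetic
    cohort generators with planted ground truth so that every stage is
    testable without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
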