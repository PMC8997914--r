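Package: csra
Title: Chemosensitivity Assay Scoring and Mutation-Resistance Association
    for Sarcoma Primary Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores plate-based chemosensitivity/chemoresistance assays
    (CSRA) on a six-step test-drug-concentration ladder into a sensitivity
    index (SI = 600 minus the summed percent inhibition), classifies primary
    tumour cultures as sensitive or resistant, restricts annotated somatic
    variants to an apoptosis-pathway gene panel, and tests the association
    between panel mutation status and per-drug resistance with one-sided
    Fisher exact tests stratified by histotype, including a
    partial-loss-of-function reassignment analysis. A synthetic cohort
    generator with known ground truth (Hill-curve dose response, planted
    mutation prevalence and odds ratio) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
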