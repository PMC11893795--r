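Package: svprior
Title: Prioritization of Rare Potentially Pathogenic Germline Structural Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying rare, potentially pathogenic
    germline structural variants (PP-SVs) in a case cohort. Implements
    dual-caller concordance filtering, cohort-level genotype quality control
    and ancestry-stratified allele-frequency estimation, breakpoint-based
    gene-impact annotation against canonical transcripts, matching to a
    known-SV table with clinical significance, a multi-tool consensus
    pathogenicity cascade with cancer gene-set filtering and a gene-role
    rule engine, variant-allele-fraction estimation from read depth and
    breakpoint evidence, and tumour loss-of-heterozygosity / second-hit
    classification. Ships a synthetic cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
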