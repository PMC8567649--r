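Package: hedstrat
Title: HLA-I Evolutionary Divergence and Joint Biomarker Stratification
    for Immunotherapy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes germline HLA class I evolutionary divergence (HED)
    from allele protein sequences using the Grantham amino-acid distance,
    derives tumor genomic features (tumor mutational burden from a
    filtered somatic SNV cascade, copy-number-alteration burden, and a
    five-locus PCR microsatellite-instability call), determines optimal
    biomarker cutpoints by maximally selected rank statistics and the
    Youden index, and runs the downstream survival, contingency,
    correlation, differential-expression and over-representation analyses
    used to evaluate HED and TMB as joint biomarkers of immune checkpoint
    blockade outcome. Includes a seeded synthetic-cohort generator so the
    whole workflow is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    limma,
    stats,
    survival,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
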