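Package: pleiocma
Title: Correlated Meta-Analysis of Family-Based Association Scans for
    Kidney Function and sRAGE
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Family-aware genome-wide and transcriptome-wide association
    scans for three correlated traits (eGFR from creatinine, eGFR from
    cystatin C, and soluble RAGE), followed by correlated meta-analysis
    (CMA) of the dependent per-trait p-values. Includes a synthetic family
    cohort generator (pedigree kinship, rare-variant genotypes, CKD-EPI
    phenotype algebra, cis-eQTL expression counts), kinship linear mixed
    model association with genomic-control diagnostics, empirical-null
    z-score correction for transcriptome scans, maximum-likelihood
    tetrachoric estimation of between-scan null correlation,
    Brown/Kost-style combination of dependent p-values, locus clumping,
    pleiotropy criteria, and novelty annotation against a catalog of
    known lead variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    pracma,
    jsonlite,
    yaml,
    edgeR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
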