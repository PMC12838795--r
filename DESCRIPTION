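Package: rvpathrx
Title: Rare-Variant Pathway Analysis of Differential Treatment Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for contrasting two clinical response groups
    by the rare damaging variants their exomes carry: genotype-level quality
    control of a cohort VCF, consensus classification of damaging missense and
    high-confidence loss-of-function variants under a gnomAD rarity filter,
    group-specific gene-set construction, pathway over-representation analysis
    with combined enrichment scores and between-group score differences,
    per-pathway carrier-burden Fisher exact tests, and a from-scratch
    covariate-adjusted SKAT-O gene-set association test with
    Benjamini-Hochberg FDR control. Includes a synthetic-cohort generator
    that emits VCF, annotation, gene-set and phenotype files with known
    ground truth, plus the exact and rank-based tests used for baseline
    clinical comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
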