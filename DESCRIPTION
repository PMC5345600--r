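Package: hapBDM
Title: Detection of Two-Locus Hybrid Incompatibilities from Haploid Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects Bateson-Dobzhansky-Muller (BDM) incompatibilities and
    heterosis from biallelic diagnostic-marker genotypes of viable and
    inviable haploid hybrids. Provides microsatellite peak scoring and
    diagnostic-marker selection, two-locus haplotype co-occurrence tables,
    adjusted contingency-table residuals, generalized
    Cochran-Mantel-Haenszel tests across marker-pair strata, an
    allele-indicator regression with marker-pair by haplotype-class
    interaction and post-hoc contrasts that classifies marker pairs as BDM,
    heterotic or neutral, a per-locus cytonuclear scan, and a seeded
    simulator of recombinant haplodiploid F2 male genotypes for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bdm.R'
    'contingency.R'
    'genotyping.R'
    'hapBDM-package.R'
    'io.R'
    'methods-HybridGenotypes.R'
    'pipeline.R'
    'simulate.R'
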