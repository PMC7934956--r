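Package: coralGxE
Title: Genotype-by-Environment Analysis of Coral Bleaching Tolerance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for multi-site coral reciprocal-transplant
    bleaching experiments. Computes site-corrected residual bleaching
    phenotypes and the associated genotype and genotype-by-environment
    ANOVAs, summarizes hourly reef temperature records (exceedance hours,
    degree heating weeks, cross-site PCA of daily means), converts
    genotype-probability triplets into expected secondary-allele dosages,
    screens loci by correlation with genotype-level bleaching residuals,
    fits a random-forest genomic predictor of bleaching tolerance with
    repeated cross-validation and a missing-data robustness procedure, and
    performs flat rank-based Mann-Whitney category enrichment of
    locus-phenotype correlations. Includes a synthetic-data generator with
    known ground truth emulating the statistical structure of a
    ten-genotype by eight-site transplant design, so every stage is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
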