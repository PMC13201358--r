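Package: prsport
Title: Cross-Population Portability of Polygenic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how polygenic scores (PRS) transfer across
    genetically distinct populations. Implements clumping+thresholding PRS
    construction over a tuning grid, incremental-R2 evaluation with
    liability-scale conversion and percentile-bootstrap confidence
    intervals, a continuous genetic-distance metric built from
    shrinkage-adjusted principal-component projection, allele-frequency
    multidimensional scaling and Procrustes alignment, a decomposition of
    relative accuracy into linkage-disequilibrium, allele-frequency and
    heritability components with loss-of-accuracy statistics, and
    recombination-rate-stratified accuracy profiles. A Gaussian-copula
    genotype/phenotype simulator generates inputs with controlled allele
    frequencies, blockwise LD, cross-population effect correlation and SNP
    heritability, so the full analysis runs end-to-end without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
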