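Package: snpladder
Title: SNP Panel Density Effects on Genomic Relationships and GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for studying how the density of
    equally-spaced SNP panels affects linkage disequilibrium summaries, the
    VanRaden genomic relationship matrix, Bayesian (Gibbs sampling) estimates
    of genetic variance under linear and liability-threshold models, and the
    accuracy and bias of genomic estimated breeding values. Includes a forward
    Wright-Fisher genotype simulator for small effective-size beef cattle-like
    populations, SNP quality-control filters with an exact Hardy-Weinberg
    test, two-locus EM estimation of haplotype frequencies and r-squared,
    a naive reference-based genotype imputation stand-in, and an end-to-end
    cross-density evaluation pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
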