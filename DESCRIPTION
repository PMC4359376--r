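Package: hzmap
Title: Genetic Mapping of Hybrid Sterility Loci and Dobzhansky-Muller
    Interactions in Admixed Hybrid-Zone Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide association mapping of hybrid-defect
    phenotypes in naturally admixed populations. Provides a
    kinship-corrected univariate linear mixed model association scan with
    Wald tests, permutation-based and false-discovery-rate significance
    thresholds, definition of significant genomic regions by linkage
    disequilibrium, restricted pairwise epistasis tests for
    Dobzhansky-Muller incompatibilities, two-locus effect-size estimation,
    genomic-region overlap permutation tests, and a two-locus
    incompatibility simulation framework for evaluating mapping power and
    false-discovery rates under nine genetic architectures. Includes a
    synthetic hybrid-zone data generator (diverged subspecies panels,
    pedigreed admixed mapping population, recombination-driven ancestry
    tracts, X hemizygosity) so every stage can be exercised without
    real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
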