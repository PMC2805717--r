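Package: stratQTL
Title: Quantifying Population Stratification and Its Impact on eQTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify population stratification in
    genotype data by projecting study samples onto a principal-component
    space built from a multi-population reference panel, and to measure the
    impact of stratification adjustment on expression quantitative trait
    locus (eQTL) mapping. Implements EIGENSTRAT-style genotype
    normalization, reference-panel PCA projection, Tracy-Widom selection of
    significant principal components, admixture-magnitude quantification,
    Kruskal-Wallis association scans with cis/trans partitioning,
    permutation-based empirical false discovery rate estimation, empirical
    relative power, a random-window pseudo-cis null, and a Balding-Nichols
    simulator for admixed cohorts with planted cis effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
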