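Package: neighborscan
Title: Selection Scans on Chemosensory Genes in Geographic-Neighbor Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing subsistence-related selection on chemosensory
    (olfactory and taste receptor) gene repertoires in paired forager and
    agriculturalist populations. Implements loss-of-function (LOF) repertoire
    profiling under a recessive model, relaxed-versus-purifying selection
    tests (windowed Tajima's D against chromosome-level neutral estimates),
    per-site Weir-Cockerham F_ST and the population branch statistic (PBS)
    with empirical-null outlier detection and FDR control, and linkage
    disequilibrium haploblock clustering of outlier SNPs. Includes a
    hierarchical Balding-Nichols cohort simulator so the full pipeline can be
    exercised and power-checked without access-restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    lme4,
    igraph,
    jsonlite,
    digest,
    VariantAnnotation,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
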