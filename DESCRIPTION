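Package: plantmet
Title: Automated Untargeted UPLC-HRMS Metabolomics Data Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An automated pipeline for untargeted metabolomic analysis of
    centroided UPLC-HRMS runs. Builds extracted ion chromatograms by ion
    density clustering, corrects baseline drift from local minima, detects
    chromatographic peaks by Gaussian-smoothing scale-space ridge lines,
    corrects retention-time shifts against an automatically chosen reference
    with a dynamic-programming alignment of peak similarity matrices,
    registers peaks across samples with a nearest-neighbour-connecting
    algorithm, screens registered components by one-way ANOVA and groups
    them into putative metabolites via outlier-robust Pearson correlation of
    peak heights, and annotates isotopologues, adducts and in-source
    fragments by within-sample ion clustering, yielding a derived mass
    spectrum per metabolite. Includes a ground-truth synthetic raw-data
    generator for benchmarking every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mzR,
    MASS,
    igraph,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
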