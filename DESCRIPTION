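Package: ampliconbench
Title: Benchmarking Framework for Differential Abundance and Beta-Diversity
    Analysis of 16S Amplicon Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: In-silico benchmarking of statistical methods for 16S rRNA gene
    amplicon (OTU) count tables. Provides a synthetic count-table generator
    reproducing the sparsity, library-size variation and overdispersion of
    real marker-gene surveys; a label-permutation protocol for measuring
    false positive rates of differential relative abundance tests; a
    spike-in engine (multiplicative, additive and mixed schemes with exact
    truth tracking and rescaling to original sequencing depth) scored by
    AUC; a roster of built-in differential abundance tests including a
    custom permutation test with statistic log(mean cases / mean
    controls)^2, plus a plugin registry for external methods; and a
    beta-diversity optimization grid sweeping library-size normalizations
    (TSS, CSS, TMM, median-of-ratios size factors), count transformations
    and distance metrics (Bray-Curtis, Euclidean, Jensen-Shannon, UniFrac,
    weighted UniFrac) scored by PERMANOVA R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vegan,
    permute,
    phyloseq,
    MASS,
    jsonlite,
    yaml,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
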