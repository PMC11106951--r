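Package: broadstates
Title: Chromatin-State Segmentation and Broad H3K4me3 Domain Analysis
Version: 0.3.1
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for CUT&RUN histone-mark and chromatin
    remodeler profiles in paired cell types: spike-in scale-factor
    normalization of binned read counts, Poisson-background binarization,
    multivariate Bernoulli-emission hidden Markov model segmentation of
    the genome into chromatin states, emission-based state labeling and
    genomic feature annotation, detection of broad (>= 4 kb) TSS-state
    domains and their genes, TMM-normalized expression with
    leave-category-out t-statistic ranking of cell-type-specific genes,
    and one-sided Fisher overrepresentation with Benjamini-Hochberg
    correction. A synthetic-data module generates a complete miniature
    study (genome, gene models, ground-truth state paths, mark counts,
    spike-ins, expression, term maps) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    edgeR,
    jsonlite,
    yaml,
    zoo,
    withr,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
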