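Package: sigconnect
Title: Cross-Study Transcriptome Comparison with Enrichment and
    Connectivity Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Compares differential-expression studies that only published
    gene lists against a study with full expression data. Published up-
    and down-regulated gene signatures are scored against a fold-change
    ranked gene list with a weighted Kolmogorov-Smirnov-like enrichment
    score, the two scores are combined into a single connectivity score,
    and significance is assessed with simulation-based null
    distributions. Also provides the surrounding pipeline: paired
    moderated differential-expression statistics, probeset-to-gene
    collapse, differentially-expressed-gene selection, k-way gene-list
    intersection (Venn) summaries, readers and writers for RNK, GMT, GCT
    and signature tables, and a synthetic two-study generator for end-to-
    end testing of cross-study concordance analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
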