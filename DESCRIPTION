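Package: fermgenomics
Title: Fermentation Functional Genomics for Lactic Acid Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fermentation functional genomics: correlate fractional
    factorial fermentation conditions with physiological phenotypes
    (Mann-Whitney U screens), associate transcriptome profiles with metabolite
    phenotypes (random-forest mean-decrease-Gini importances) and with maximum
    growth rate (an iterative grouped-gene correlation algorithm), run
    Bayesian-regularized (CyberT-style) differential expression with
    Benjamini-Hochberg FDR control, reconstruct condition-response regulatory
    networks with hypergeometric functional-class enrichment, and discover
    inverted-repeat transcription-factor binding motifs in promoter regions.
    Includes a synthetic-study generator with planted structure so every stage
    of the pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
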