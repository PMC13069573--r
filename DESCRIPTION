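Package: nevar
Title: Inter-Individual Expression Variability and Gene Duplication Retention
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies inter-individual gene expression variability from
    replicated expression profiles and relates it to gene duplication mode.
    Computes the squared coefficient of variation per gene and timepoint,
    normalizes it against a locally fitted mean-variance trend to obtain
    normalized expression variability (NEV), and summarizes genes by their
    median NEV across timepoints. Companion tools compute environmental
    responsiveness from a treatment/baseline expression atlas, the tau
    tissue-specificity index, rank-based group contrasts with Cliff's delta
    effect sizes, within-pair divergence statistics for small-scale (SSD)
    versus whole-genome (WGD) duplicates, derived/ancestral age asymmetry
    from phylostratigraphic clade assignments, information-content-based
    semantic similarity between paralog annotations (Jiang measure,
    best-match average), and hypergeometric term enrichment with FDR
    control. A seeded synthetic-data generator with recorded ground truth
    makes every stage testable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
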