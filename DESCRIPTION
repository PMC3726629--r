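Package: mlxtools
Title: Analysis Pipeline for Male-Limited X-Chromosome Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for male-limited X-chromosome (MLX)
    experimental evolution studies in Drosophila: per-transcript nested
    ANOVA (Treatment fixed, Population random nested within Treatment)
    with Benjamini-Hochberg false discovery rate control, a six-way
    treatment-pattern transcript classifier, enrichment batteries
    (hypergeometric GO tests, chromosomal chi-square, tissue-specific
    Fisher tests with Bonferroni correction, two-tailed mean-rank gene
    set enrichment), a direction-of-change test for feminization of
    paternally inherited X-chromosomes, population-mean ANOVAs for
    competitive fitness and sex-ratio assays, a forward-time
    individual-based simulator of the compound-X (DX) female
    transmission scheme, and a synthetic-data generator that emulates
    the full experimental design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
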