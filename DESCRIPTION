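Package: coexscreen
Title: Guide-Gene Co-Expression Screening for Pathway Regulator Discovery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Transcriptome co-expression network analysis for guide-gene
    ("guilt-by-association") discovery of pathway regulators in segregating
    populations. Reads RPKM expression matrices, filters expressed genes and
    counts fold-change differential expression against comparator genotypes,
    builds hard-thresholded Pearson correlation networks over flavonoid
    pathway guide genes with two-tailed t-test significance, screens
    transcription-factor candidates by positive-link counts, quantifies
    qRT-PCR readouts by the 2^-delta-delta-Ct method with primer-efficiency
    estimation, and simulates RPKM populations with planted correlation
    structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
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
    withr
Config/testthat/edition: 3
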