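Package: miredit
Title: Detection and Quantification of A-to-I MicroRNA Editing from
    Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for studying ADAR-mediated A-to-I
    editing of mature microRNAs in bulk small-RNA sequencing data.
    Provides a negative-binomial read simulator with planted per-site
    editing fractions and group abundance effects, adapter/quality read
    cleaning and collapsing, mismatch-tolerant 5'-anchored mapping to a
    mature-miRNA reference, per-position mismatch profiling and A-to-G
    editing-site calling with seed-region (nt 2-7) classification,
    median-of-ratios count normalization with tiered two-group
    differential-expression tests, Pfaffl/delta-delta-Ct relative
    quantification with ANOVA and Tukey post-hoc analysis, and
    substitution calling in Sanger-sequenced clones of mature miRNAs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
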