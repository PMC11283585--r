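Package: pairscreen
Title: Analysis of Dual-Guide CRISPR-Cas12a Combinatorial Knockout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled double-knockout screens built on dual-spacer
    CRISPR-Cas12a crRNA arrays. Enumerates a combinatorial array library
    (kinase x metabolism double knockouts plus single-knockout and
    non-targeting controls), reconstructs array cassettes from paired-end
    amplicon reads by exact overlap merging, counts arrays and normalizes to
    reads per million, and calls genetic interactions with two models: a
    studentized-residual outlier test on expected versus observed
    double-knockout enrichment under non-targeting-control normalization, and
    a Wilcoxon rank-sum comparison of double- versus single-knockout
    fold-changes. Also implements a virtual double-knockdown survival screen
    that stratifies an expression cohort by quartiles of pair-mean expression
    and scores gene pairs by log-rank p-value ratios, and ships synthetic-data
    generators (negative-binomial screen counts, paired FASTQ, survival
    cohorts) so the whole pipeline is testable without external data.
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
    purrr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
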