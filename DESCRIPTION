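Package: methylrrbs
Title: Tidy Downstream Analysis of RRBS Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of reduced representation bisulfite
    sequencing (RRBS) methylomes in both CpG and CpH contexts: coverage and
    co-existence filtering of per-cytosine count files, CpG-island detection
    with shore/shelf derivation, strand-aware genic feature annotation,
    binned metagene and island methylation profiles, megabase window tracks,
    site-level differential methylation calling (two-tail Fisher exact test
    with a methylation-difference threshold and FDR control), region-level
    differential methylation of islands and genes (Student's t on replicate
    means), genomic feature and QTL enrichment statistics, and a seeded
    synthetic RRBS methylome generator with known ground truth for
    validation. All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
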