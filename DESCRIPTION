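Package: teinsite
Title: Transposon-Insertion-Centric Chromatin and Expression Analysis
Version: 0.1.0
Authors@R:
    person("teinsite", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable building blocks for analysing transposable-element
    (TE) silencing from aligned sequencing data: exact k-mer genome
    mappability tracks (single-read and paired-fragment), strand-aware
    unique-read counting over genes and TE consensus sequences with
    median-of-ratios normalisation and a thresholded de-repression
    classifier, promoter-to-insertion proximity annotation, 1-kb
    mappability-filtered chromatin bin comparison between knockdown and
    control ChIP-seq libraries, insertion-anchored meta-profiles with
    bootstrap confidence intervals, and a deterministic synthetic-data
    generator with planted effects that makes every stage testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
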