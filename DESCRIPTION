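Package: dmetr
Title: Case-Control Association Analysis for DMET Pharmacogenomic Genotype Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads probes-by-samples genotype tables in the layout exported by
    the Affymetrix DMET (drug metabolism enzymes and transporters) platform,
    tests each probe's genotype distribution between two sample classes with
    exact Fisher tests (per-genotype 2x2 or omnibus 2xk, with an optional
    frequency-difference pre-filter and Bonferroni or Benjamini-Hochberg
    correction), tests Hardy-Weinberg equilibrium for bi-allelic probesets by
    Pearson's chi-square, annotates markers with rsIDs and offline dbSNP and
    PharmGKB links, encodes genotype heatmaps, and simulates DMET-format
    case-control datasets with known null and associated structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
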