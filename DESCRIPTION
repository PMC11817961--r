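Package: ssrkit
Title: Microsatellite Mining, Marker Evaluation, and SSR-Based Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A genome-to-fingerprint toolkit for simple sequence repeat (SSR)
    markers. Mines perfect microsatellites from genome sequence with
    MISA-style thresholds, classifies repeat motifs into canonical
    rotation/reverse-complement classes, evaluates candidate primer pairs and
    virtually amplifies them against a genome (in-silico PCR), computes
    per-locus diversity (Na, Ne, Ho, He, Shannon I, PIC) and identity (PI,
    PIsibs) statistics from fragment-size genotype tables, builds similarity
    matrices, Mantel tests, principal coordinate embeddings and distance
    trees, infers admixture proportions by maximum-likelihood EM with Evanno
    delta-K model choice, and emits per-individual DNA fingerprint codes under
    zygosity and 10-bp-bin encodings, including minimal discriminating marker
    set selection. Includes simulators for genomes with planted SSR ground
    truth and structured diploid genotype panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
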