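Package: sweepsets
Title: Polygenic Selection Scans and Permutation Gene-Set Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects polygenic adaptation by combining SNP-level selection
    scans with permutation-based gene-set enrichment. Implements a
    haplotype-homozygosity scan (EHH decay, integrated haplotype
    homozygosity, standardized iHS) and a cross-population
    composite-likelihood-ratio scan (XP-CLR style drift/sweep mixture model
    over a physical grid), consensus SNP-to-gene assignment over longest
    isoform unions, gene-set collection hygiene (size filtering,
    similarity-based merging), two permutation enrichment engines
    (sum-of-gene-scores with bias-matched nulls and overlap pruning;
    candidate-SNP counting with genome-wide SNP permutation),
    Benjamini-Hochberg q-values, and disease-gene outlier flagging.
    A forward Wright-Fisher simulator with recombination and planted
    selective sweeps generates fully synthetic inputs so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    yaml,
    vcfR,
    fgsea,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
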