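Package: bsaqtl
Title: Bulked-Segregant QTL-Seq Mapping with Simulation-Based Confidence Bands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for QTL-seq bulked-segregant analysis of biparental
    selfing populations. Computes a relative-response phenotype statistic
    from treated/control fresh weights, selects extreme phenotypic tails
    into bulks, turns pooled allele counts into per-site SNP-index and
    delta SNP-index tracks, smooths them with a sliding-window genome
    scan, and calls candidate regions against two-sided Monte-Carlo
    confidence bands simulated for an F3 two-bulk design across a grid of
    sequencing depths. A seeded biparental-cross simulator (meiosis under
    Haldane's map function, F1 selfed to F2 selfed to F3, quantitative
    trait with a planted QTL, two-stage pooled read sampling) provides
    ground-truth data so every stage is testable without raw sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    tools,
    yaml,
    ggplot2
Suggests:
    withr,
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
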