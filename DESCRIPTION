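Package: svbench
Title: Construction and Use of Haplotype-Resolved Structural Variant Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building a high-confidence structural variant (SV)
    benchmark from multi-platform long-read callsets and for evaluating
    arbitrary callsets against it. Implements pairwise SV match predicates
    (breakpoint distance, size ratio, reciprocal overlap, sequence
    divergence) and deterministic cross-platform merging; repeat-region
    exclusion and tiered retention rules for high-confidence call
    integration; trio-binning of child long reads by parent-unique k-mers
    with a multi-k vote; construction of continuous high-confidence regions
    (CHCRs) from haplotype-assembly support; Sanger concordance scoring;
    precision/recall/F1 evaluation within confident regions, replicate
    consensus merging and benchmark-to-benchmark comparison; and seeded
    synthetic trio generators (reference, diploid haplotypes, platform
    callsets, error-bearing reads) used as the test bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
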