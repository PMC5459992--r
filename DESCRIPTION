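Package: transmeth
Title: Transgenerational Sperm Methylome and Addiction-Behaviour Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores cocaine self-administration cohorts (fixed-ratio lever
    pressing, progressive-ratio break points, combined z-score) and classifies
    animals into Addict and Non-addict phenotypes; tests per-CpG differential
    methylation between phenotypes from RRBS-style coverage tables with a
    pooled-count exact test and Benjamini-Hochberg correction; intersects
    F0 and F1 results into direction-consistent maintained differences;
    annotates CpGs to promoters, exons and introns; computes hypomethylation
    and promoter enrichment odds ratios, metagene methylation profiles and
    classical MDS embeddings; and overlaps maintained promoter methylation
    with offspring differential expression. A synthetic-data module generates
    operant session logs and beta-binomial methylation matrices with planted
    effects so every stage is verifiable against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
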