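Package: rddmr
Title: Bin-Based DMR, Differential siRNA Region and Expression Analysis
    for RdDM Studies
Version: 0.1.0
Authors@R:
    person("Packages", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for studying RNA-directed DNA methylation
    (RdDM) with paired wild-type/mutant sequencing libraries. Implements
    bin-based differentially methylated region (DMR) calling from
    whole-genome bisulfite cytosine reports in the CG, CHG and CHH
    contexts (Fisher's exact test on pooled bin counts,
    Benjamini-Hochberg correction, context-specific methylation
    difference thresholds, gap-joining of significant bins), differential
    24-nt siRNA region (DSR) calling from RPTM-normalized 100-bp bin
    counts, differential gene/TE expression via an exact conditional
    binomial rate test, and the downstream region-set analyses: genomic
    feature partition, overlap and total-length accounting, DMR-DSR delta
    correlation, chromatin-state enrichment, DEG-DMR flank association
    and promoter methylation aggregation. Ships a synthetic-data
    generator that plants known methylation, siRNA and expression effects
    at RdDM-like loci so every stage of the pipeline can be benchmarked
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
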