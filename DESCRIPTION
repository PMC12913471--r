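Package: methexpr
Title: Whole-Genome Bisulfite Methylation Analysis with Expression Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative whole-genome bisulfite sequencing (WGBS)
    analysis in plants: cytosine context classification (CG/CHG/CHH) against a
    reference genome, parsing and coverage filtering of per-cytosine
    methylation reports, window-based differentially methylated region (DMR)
    calling with a two-sided Fisher exact test (>= 5 context sites, >= 2-fold
    level change, P <= 0.05), metagene methylation profiles over scaled
    gene/transposon bodies with 2 kb flanks, expression-rank stratified
    profiles, genome partitioning into promoter/exon/intron/intergenic
    classes, and methylation-expression correlation summaries (FPKM,
    2^-ddCt). Includes a fully seeded synthetic-data generator (genome,
    annotation, planted DMRs, binomial bisulfite counts with non-conversion
    error, negative-binomial expression coupled to promoter methylation) so
    the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    graphics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
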