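Package: cdpkfam
Title: Genome-Wide Survey of Calcium-Dependent Protein Kinase Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide identification and characterisation of
    calcium-dependent protein kinase (CDPK) gene families. Family membership
    is called from domain architecture (Ser/Thr kinase catalytic triad
    followed by 1-4 EF-hand calcium-binding loops), N-terminal myristoylation
    and palmitoylation motifs are predicted from PROSITE-style rules,
    neighbor-joining phylogenies with bootstrap supports assign members to
    subfamily groups, duplicated gene pairs are detected by alignment
    coverage/identity criteria and classified as tandem or segmental,
    exon-intron structures and intron phases are derived from gene models,
    and qRT-PCR Ct tables are quantified by the delta-delta Ct method with
    complete-linkage hierarchical clustering of expression profiles. A
    seeded synthetic-genome generator provides ground-truth data for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    ape,
    rtracklayer,
    BiocGenerics,
    GenomicRanges,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
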