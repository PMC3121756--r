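Package: haplozein
Title: Haplotype Analysis of Tandem Alpha-Zein Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of maize alpha-zein (prolamin)
    gene-family haplotypes: molecular-clock dating of LTR retroelement
    insertions (Kimura two-parameter divergence between paired LTRs) and of
    tandem gene duplications (Nei-Gojobori synonymous substitution rates),
    distance-based paralog phylogenies (neighbor joining, UPGMA, bootstrap),
    paralog-specific transcript attribution from randomly sequenced cDNA
    clones, per-cytosine bisulfite methylation profiling of promoters in
    CG/CHG/CHH contexts, promoter cis-element scanning (prolamin box,
    Opaque2 site), gene-copy status classification, haplotype composition
    and conservation summaries, and nested-insertion chronologies. Includes
    a synthetic haplotype simulator with a complete truth ledger so every
    analytical stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
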