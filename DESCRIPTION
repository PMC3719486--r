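Package: famwave
Title: Gene Family Expansion Waves: Simulation, Phylogeny-Based
    Classification and Selection Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the birth-death evolution of large plant
    gene families such as the F-box FBA subfamily. Includes a seeded
    birth-death simulator with lineage-specific duplication waves, MG94-style
    codon sequence evolution with per-domain selection (omega), tandem versus
    dispersed chromosomal placement and category-linked expression profiles;
    JTT maximum-likelihood protein distances, neighbor joining with bootstrap
    consensus supports and outgroup rooting; extraction of supported clades
    and stable/unstable/singleton classification; Dollo reconstruction of
    ancestral gene counts and per-branch gains and losses on a species tree;
    Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction,
    sliding windows and domain contrasts; tandem cluster detection from gene
    coordinates; and expression preprocessing, UPGMA clustering and
    clade-versus-expression concordance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
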