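Package: ddscan
Title: Sort-Seq Analysis of Combinatorial Kinase Docking-Domain Libraries
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sort-seq screens of combinatorially randomised
    protein docking domains, modelled on a six-position MAP kinase kinase
    (MKK1) D-domain library sorted into low/medium/high activity gates.
    Provides the combinatorial library design calculus (library size,
    mutational neighbourhoods, coverage probability, recovery-PCR cycles), a
    ground-truthed synthetic sort-seq generator with a planted hydrophobic
    Phi-X-Phi synergy, variant extraction from merged amplicon reads with
    degenerate-reference Needleman-Wunsch alignment and insertion-aware
    genotype calling, per-gate counting with read cutoffs and active-set
    filtering, position-wise and pairwise enrichment and epistasis statistics
    with chi-squared independence tests, and Hamming-distance-1 sequence
    similarity networks with Leiden/Louvain community detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, Software, StatisticalMethod
RoxygenNote: 7.3.3
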