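Package: genescout
Title: Assembly-Free Detection of Gene Presence, Degradation and Loss
    from Raw Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects presence, degradation or loss of protein-coding
    genes (such as the rodent CD1 lipid-antigen-presenting family)
    directly from raw shotgun sequencing reads, without genome assembly.
    Provides a six-frame translated Smith-Waterman search of protein
    queries against DNA reads with Karlin-Altschul E-values and
    BLAST/DIAMOND outfmt-6 compatible tables, per-query-position best-hit
    profiling, tiered read filtering and translation, reference-guided
    protein reconstruction with per-residue evidence, three-state
    presence calling, a rank-based (Mann-Whitney U) comparison of
    stop-codon-free normalized peptide lengths, identity-distance
    neighbor-joining trees over antigen-presenting regions, parsing of
    structure-prediction confidence outputs (per-residue pLDDT and PAE
    matrices), and a fully seeded synthetic-data generator for
    ground-truthed benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    bio3d,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
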