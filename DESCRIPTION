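Package: panplastome
Title: Comparative Pan-Plastome Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative analysis of annotated chloroplast genomes
    (plastomes): detection of the quadripartite LSC/SSC/inverted-repeat
    architecture from sequence or read-coverage evidence, extraction of genic
    and microsynteny-conserved intergenic regions across samples, per-region
    alignment identity and SNV/InDel landscapes with reading-frame analysis,
    trimmed and codon-partitioned supermatrix construction with diagnostic
    marker selection and a neighbor-joining tree, alignment-free phylogenetic
    splits from kmer presence patterns with greedy compatible-tree extraction,
    and quantitative split-set/tree comparison (weighted precision, recall,
    F1, Robinson-Foulds). Includes a tree-conditioned plastome evolution
    simulator that emits annotated sequences, true alignments, true indel
    records and coverage tracks as ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    Biostrings,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
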