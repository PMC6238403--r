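Package: LTRcensus
Title: Structural Detection, Family Building and Clade Classification of
    LTR Retrotransposons
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable census pipeline for LTR retrotransposons in
    assembled genomes. Detects candidate elements de novo from paired long
    terminal repeats, classifies them into the Copia, BEL/Pao and Gypsy
    superfamilies by translated similarity search against a labelled
    RT/RNaseH reference panel, builds families under the 80-80-80 rule with
    copy curation and cluster merging, re-annotates genomes with the family
    library to recover degraded and solo-LTR copies with hit
    defragmentation, reconstructs RT/RNaseH neighbor-joining phylogenies
    with bootstrap support to define clades, assigns unplaced families to
    clades by a five-best-hit similarity rule, and summarises the census as
    superfamily and clade composition tables. A synthetic-genome generator
    with a planted truth set makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
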