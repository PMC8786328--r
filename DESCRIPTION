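Package: pirnakit
Title: Density-Based piRNA Cluster Discovery, Ping-Pong Signature
    Detection and Target Prediction for Small-RNA Data
Version: 0.1.0
Authors@R:
    person("pirnakit", "developers", email = "pirnakit@example.org",
           role = c("aut", "cre"))
Description: Analytical toolkit for PIWI-interacting RNA (piRNA) datasets:
    redundancy collapse and species-prefixed ID assignment for aligned
    small-RNA reads; data-driven DBSCAN clustering of piRNA loci into
    scored, strand-classified genomic clusters with k-distance based
    epsilon estimation; detection of ping-pong partner pairs via the
    characteristic 10-nt 5' overlap and the corresponding overlap-length
    signature; genomic-context annotation of loci and clusters against
    gene models, repeats, pseudogenes and lncRNAs, including synteny-block
    remapping; counts-per-million normalization with z-score expression
    screening; and anticorrelation-gated piRNA target prediction using a
    wobble-aware local complementarity aligner with nearest-neighbor
    duplex free-energy estimation. A deterministic simulator with planted
    ground truth supports validation of every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
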