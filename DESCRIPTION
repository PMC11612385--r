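Package: CloneClub
Title: Clonotype-Level Integration of Single-Cell Expression and TCR
    Embeddings to Identify Functionally Similar T-Cell Clubs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Groups T-cell clones (cells sharing a CDR3beta sequence within a
    sample) into "clubs" of functionally similar clones by integrating paired
    single-cell gene expression and TCR sequence embeddings. A local-harmony
    block-coordinate optimization fits per-clone regression coefficients and
    per-dimension embedding weights so that weighted embedding similarities
    explain clone-pairwise expression similarities on each clone's nearest
    neighbors; the residual-distance matrix at convergence drives a
    structural-entropy divisive hierarchy whose leaves are the clubs, and a
    consensus over stochastic restarts yields the final partition. Includes
    readers for 10x-style contig tables and MTX count matrices, repertoire
    evaluation metrics (clustering purity, coverage, effectiveness), concept
    scores, club annotation helpers, and a synthetic paired-data generator
    with planted club structure, clonal expansion and dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    mclust,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
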