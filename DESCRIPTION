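Package: mycoscan
Title: Gut Mycobiome Profiling, Differential Abundance, Co-Occurrence
    Networks and Classification from Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained pipeline for fungal (mycobiome) analysis of
    shotgun metagenomes: curation of a non-redundant fungal genome catalog
    (assembly quality filters, k-mer decontamination, MinHash ANI
    clustering at the 95 percent species boundary), paired-read quality
    control, genome-size normalized TPM abundance profiling with taxonomic
    roll-up, community statistics (alpha diversity, Bray-Curtis, PCoA,
    PERMANOVA), two-group differential abundance with LDA effect sizes
    and fold-change filters, random-matrix-theory thresholded
    fungal-bacterial co-occurrence networks with topology metrics, and
    repeated cross-validated random-forest and LASSO classification.
    Ships a synthetic-data module (genomes at controlled nucleotide
    identity, error-bearing paired reads, two-group abundance studies
    with planted effects) so the whole pipeline is testable without
    external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    igraph,
    glmnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    Rsamtools,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
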