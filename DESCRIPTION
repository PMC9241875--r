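Package: panogri
Title: Pangenome Openness, Genome Relatedness Indices, and Genospecies
    Delineation for Bacterial Genera
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics toolkit for genus-level bacterial
    taxonomy: greedy centroid clustering of proteins into gene families,
    core/accessory/unique pangenome partitioning with permutation
    rarefaction curves and Heaps'-law openness fitting, fragment-based
    average nucleotide identity (ANI) and digital DNA-DNA hybridization
    (dDDH, formula-2 style), threshold-based genospecies and genus
    delineation with conflict detection, neighbor-joining phylogenetics
    under the Kimura two-parameter model with bootstrap support, and
    detection plus rule-based typing of carotenoid (crt) gene
    neighborhoods.  A synthetic-genome generator provides gene-content
    matrices, divergent genome pairs, protein families and annotated crt
    neighborhoods with known ground truth, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    pheatmap,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
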