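Package: panclade
Title: Pangenome and Clade-Structure Analysis for Bacterial Genome Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end comparative-genomics toolkit for resolving the
    population structure of a bacterial species from genome assemblies and
    protein annotations. Computes average nucleotide identity (fragment-based
    ANIb and maximal-match ANIm) and the hybrid intra/inter-species distance
    matrix, clusters proteins into gene families at identity/coverage
    thresholds, builds the ternary presence/fragmentation/absence pangenome
    matrix with rarefaction and group-resampling statistics, extracts a
    core-genome SNP and indel supermatrix, reconstructs neighbor-joining trees
    from Kimura 2-parameter distances with bootstrap support, and profiles
    clade-specific gene content, variable regions, pathway completion and
    phosphotransferase-system components. A synthetic-genome generator with a
    known clade tree, gene gain/loss, pseudogenization and planted
    clade-specific operons provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    Matrix,
    methods,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
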