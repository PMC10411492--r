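Package: phyloconflict
Title: Chromosome-Aware Interrogation of Gene-Tree Conflict
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting phylogenomic gene-tree conflict by
    chromosomal linkage. Implements a locus-hygiene cascade (long-branch
    paralog removal, cross-contamination drop-tests, sequence-distance and
    Robinson-Foulds outlier filters), read-depth confirmation of X-linkage
    from sexed samples, a GTR+Gamma pruning-likelihood engine for per-locus
    per-base phylogenetic signal around focal edges of a species tree,
    third-codon-position (NT12) correction of saturation-driven signal,
    weighted Robinson-Foulds grove clustering of gene trees via principal
    coordinates, and a synthetic-data generator emulating a faster-X
    phylogenomic data set for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Rcpp,
    seqinr,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
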