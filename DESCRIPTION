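Package: metadiv
Title: Coverage-Standardized Taxonomic and Phylogenetic Diversity for
    Metabarcoding Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A workflow for diversity analysis of sample-by-OTU read-count
    tables from DNA metabarcoding. Provides a Good-Turing singleton-error
    filter that estimates the true number of singletons per sample from
    higher frequency counts and removes the surplus by seeded random
    deletion; Turing sample-coverage estimation with rarefaction and
    extrapolation of the coverage curve; taxonomic and phylogenetic Hill
    numbers (q = 0, 1, 2) standardized to a target sample coverage;
    assembly of a dated ultrametric phylogeny by grafting neighbour-joining
    barcode subtrees onto a family-level backbone with bladj-style fossil
    age calibration; coverage-standardized pairwise dissimilarities
    (Jaccard, Horn, Morisita-Horn) and multiple regression on distance
    matrices with permutation inference; and seeded simulators for every
    input, with known ground truth, for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    phytools,
    cluster,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
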