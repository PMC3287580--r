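Package: svdtax
Title: Alignment-Free Taxonomic Clustering of Proteomes via Trigram SVD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Groups species by the amino-acid trigram composition of their
    concatenated protein sequences. Each proteome becomes an 8000-entry
    trigram count vector; truncated singular value decomposition projects
    species into a rank-k latent space where Euclidean distances drive a
    simple threshold agglomerative clusterer (ASAP). A recursive parameter
    search (kdcSearch) sweeps rank, distance threshold and cluster count,
    gates configurations on the isolation of a positive-control species
    group, and ranks surviving configurations by the median of a
    Linnaean-taxonomy cluster-quality score (cLtlf). Includes PHYLIP
    distance-matrix export, neighbor-joining cladogram output, a seeded
    k-means comparison harness, and a synthetic clade simulator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
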