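Package: mirrorcoev
Title: Mirror-Tree Coevolution Analysis of Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers protein-protein coevolution from species-labelled protein
    alignments with the mirror-tree method: uncorrected pairwise p-distance
    matrices are computed for two families over their common species, the
    strict upper triangles are correlated by the Pearson method, and candidate
    interaction partners are ranked with Fisher r-to-z tests for the
    significance of, and difference between, correlation coefficients. Also
    provides alignment conservation profiling with kinase consensus-context
    scanning of candidate tyrosine and serine phosphosites, and a
    correlated-rate sequence-evolution simulator (Yule trees, lognormal branch
    rates with a tunable coevolution coefficient) that supplies ground-truth
    inputs for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
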