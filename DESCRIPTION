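Package: seqsmith
Title: K-mer Seed-and-Extend Homology Search and Sequence Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for k-mer based homology search and
    general sequence analysis. Sequence databases are indexed into k-mer
    tables (contiguous or spaced seeds), seed matches are filtered with a
    two-hit strategy and extended with ungapped X-drop, gapped X-drop and
    banded affine-gap alignments, and hits are ranked by Gumbel E-values
    fitted by the method of moments. Also provides rigorous
    Needleman-Wunsch/Smith-Waterman alignment with affine gaps (Gotoh),
    sequence profiles (PFM/PPM/PWM, consensus), distance-based guide trees
    (UPGMA, neighbor-joining) with Newick serialization, progressive
    multiple sequence alignment, and seeded generators for synthetic
    benchmark data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
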