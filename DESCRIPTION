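Package: psrniche
Title: Phylogenetic Signal-Representation Curves for Haplotype Bioclimatic
    Niches
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects phylogenetic niche conservatism at the haplotype scale.
    Collapses aligned chloroplast marker sequences into haplotypes with coded
    indel events, computes Tajima-Nei distances, extracts principal-coordinate
    eigenvectors, and fits Phylogenetic Signal-Representation (PSR) curves for
    bioclimatic variables by phylogenetic eigenvector regression. Summarises
    each curve as a signed area against the Brownian-motion diagonal with
    permutation nulls, detects R-squared peaks, and overlays eigenvector ranks
    on median-joining haplotype networks. Includes a coalescent-based
    synthetic-data generator with Brownian-motion, Ornstein-Uhlenbeck and
    early-burst trait models for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
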