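Package: lcnbarcode
Title: Evaluation of Two-Part (Exon+Intron) DNA Barcoding Markers in
    Low-Divergence Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate low-copy nuclear DNA barcoding markers that
    combine a slowly evolving exon with an adjacent indel-rich intron, as
    used for species identification in recently radiated plant groups such
    as the Bromeliaceae. Provides greedy incremental identity clustering
    (CD-HIT-EST style), Kimura 2-parameter distances with pairwise deletion,
    barcoding-gap assessment with an exact/approximate Wilcoxon rank-sum
    test, megablast-style seeded local alignment with Karlin-Altschul bit
    scores and E-values, a best-hit species identification rule with
    unique-top-score semantics, neighbor-joining trees with bootstrap
    support, hybrid detection by allele-to-genepool assignment, and a
    seeded simulator of exon+intron marker datasets with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
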