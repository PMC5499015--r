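Package: katcensus
Title: Genome-Scale Census of Lysine Acetyltransferase and Deacetylase Families
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-scale surveys of lysine
    acetyltransferase (KAT) and lysine deacetylase (KDAC) protein families
    across photosynthetic eukaryotes. Builds position-specific profile models
    from seed alignments, scores candidate proteomes with seeded Gumbel
    E-value calibration and explicit accept/review/reject E-value zones,
    validates review-zone hits by reciprocal best hit, tabulates family sizes
    per species and compares them across species types (Kruskal-Wallis).
    Summarises domain architectures as median-length-scaled positional
    histograms with a prevalence display filter, derives consensus
    subcellular localizations from five predictor calls by 3-of-5 majority
    voting, and tests promoter cis-element enrichment (2000 bp strand-aware
    upstream regions, exact non-overlapping motif matches, hypergeometric
    upper tail) with a cross-species conservation filter. A synthetic-data
    generator plants known family members, motifs, domains and localizations
    so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    graphics,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
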