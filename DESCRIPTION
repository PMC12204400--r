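Package: codonPassenger
Title: Synonymous Codon Enrichment and Passenger-Effect Diagnostics for
    Transgene Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing 5' synonymous codon composition in large
    transgene construct libraries. Computes per-codon synonymous-block
    log-odds enrichment vectors between highly and lowly expressed
    construct sets (with the modified Haldane-Anscombe zero-cell
    correction), positional and 5'-versus-core variants, and concordance
    statistics between datasets (orthogonal fits, within-block oriented
    pairwise comparisons, best-codon matrices with weighted binomial
    tests). Provides a diagnostic suite for "passenger effects" -- the
    distortion of a codon's apparent enrichment caused by non-random
    co-occurrence with causally effective codons in the same constructs:
    focal-codon-exclusion mean-of-means profiles, codon co-occurrence
    observed/expected statistics with subsampled chi-squared nulls, and
    residual attribution of between-dataset disagreement. Also includes
    per-construct 5' feature computation with partial Spearman
    correlations and LMG relative-importance decomposition, and a seeded
    synthetic construct-library generator with controlled randomization,
    planted design bias and a stated expression model, so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
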