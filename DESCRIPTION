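Package: mitofidelity
Title: Codon-Level Analysis of Mitoribosomal Misreading Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing translational fidelity at the codon level in
    mitochondrial (and other) genomes. Enumerates cognate and near-cognate
    codon neighbourhoods under arbitrary NCBI genetic-code tables, counts
    their occurrences in coding sequences, and computes the discrimination
    ratio that identifies endogenous reporter proteins of ribosomal
    misreading (such as human MT-CO1, whose cysteine/methionine codon
    composition makes label incorporation sensitive to near-cognate
    decoding errors). Also provides stop-codon context analysis for hungry
    codons and -1 frameshift sites, read-through product prediction with
    poly-lysine tract and molecular-weight computation, a quantitative
    first-order model linking per-codon misreading probability to observable
    dual-label incorporation ratios (closed form, Monte Carlo simulator and
    inverse fit), dual-reporter assay normalisation, and synthetic-data
    generators with exactly planted codon compositions for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
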