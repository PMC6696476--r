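Package: hnoxscout
Title: Flexible-Gap Motif Discovery and Heme Spectral-State Analysis for
    Candidate NO-Binding Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for discovering candidate nitric-oxide-binding proteins
    that carry a reduced Heme Nitric Oxide/Oxygen (H-NOX) center. Implements
    a PROSITE-style flexible-gap motif grammar (parsing, canonicalisation,
    relaxation by dropping fixed residues), consensus-motif extraction from
    alignments of functional centers with annotated critical columns,
    exhaustive flexible-gap proteome scanning with locus-level candidate
    aggregation, and a rule-based classifier of heme UV/Vis spectral states
    (Soret and alpha/beta bands) with NO-titration saturation detection and
    dissociation time-series analysis. Ships seeded synthetic-data
    generators (planted proteomes, state-templated spectra, titration and
    dissociation series) that provide exact ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
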