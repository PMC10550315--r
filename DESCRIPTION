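Package: tadpred
Title: Mechanistic Prediction of Acidic Transcriptional Activation Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts acidic transcriptional activation domains on
    transcription factor proteins from the clustering of acidic (D, E) and
    aromatic/leucine (W, F, Y, L) residues in fixed-length sliding windows.
    Provides tiling of proteomes into 39-residue windows with per-window net
    charge and residue counts, parametrized boundary classifiers over the
    (net charge, hydrophobic count) plane with diagonal, corner, and
    trapezoid geometries, aggregation of passing windows into predicted
    domains, curation and composition-based classification of annotated
    activation-domain lists, interval-overlap benchmarking with
    length-distribution-preserving permutation nulls, intersection with
    external prediction sets, and a synthetic proteome generator with
    planted domains for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
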