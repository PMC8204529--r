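Package: sopsrel
Title: Inter-Rater Reliability Analysis for SOPS Subthreshold Psychosis Ratings
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-rater reliability studies of the Scale of
    Prodromal Symptoms (SOPS), the 19-item ordinal severity scale that
    accompanies the Structured Interview for Prodromal Syndromes (SIPS).
    Provides instrument-aware loading, validation and summary scoring of
    long-format rating tables; rule-based classification of subthreshold
    psychotic symptom status (positive, negative/disorganized, combined,
    and acute positive categories); intraclass correlation ICC(A,1)
    estimation (two-way random effects, single measures, absolute
    agreement) with F-based confidence intervals, including a
    method-of-moments variance-component route for incomplete subject by
    rater designs that uses all observed cells without imputation; a
    synthetic multi-rater data generator with known latent variance
    structure, severity mixture, and interview-order missingness; and a
    study pipeline producing scale-, item-, and status-level reliability
    reports with clinical high risk (CHR) stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
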