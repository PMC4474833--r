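Package: isoturn
Title: Proteome Turnover Kinetics from 15N Pulse Labeling, Dual-Isotope
    MS1 Quantification and Modification-Aware tRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring protein synthesis rates in bacteria by
    15N pulse labeling. Converts MS1 14N/15N peptide area ratios into
    per-protein synthesis rate constants and half-lives under a
    steady-state proteome model, with censoring of unreliable long
    half-lives. Includes the supporting dual-isotope peptide chemistry
    (in-silico tryptic digestion, elemental composition, isotope
    envelope prediction by convolution, precursor-mass candidate lookup
    and MS1 area-ratio quantification), a modification-aware semi-global
    aligner for tRNA sequencing reads with spike-in normalization,
    per-species fold changes and 3'-truncation profiling, growth-curve
    and delta-delta-Ct statistics, and seeded synthetic-data generators
    for every input so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
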