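Package: crisprquant
Title: Quantification of CRISPR Editing Outcomes from Amplicon Sequencing
    and In Vitro Cleavage Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify genome-editing outcomes from amplicon
    deep-sequencing reads: semiglobal alignment of reads to reference
    amplicons, classification of reads into indel, base-edit, prime-edit
    and dsODN-tag outcome classes, per-sample outcome frequencies, base
    editing window/bystander profiles, off-target specificity metrics,
    and estimation of in vitro cleavage kinetics (one-phase exponential
    decay rate constants and active-enzyme fractions from titrations).
    Includes a synthetic read and time-course simulator with ground-truth
    tables for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
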