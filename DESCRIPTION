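Package: chclone
Title: Clonal Hematopoiesis Calling and Dose-Response Analysis for
    Radioactive Iodine Therapy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing clonal hematopoiesis (CH) detected by
    error-corrected sequencing in thyroid-cancer cohorts stratified by
    cumulative radioactive iodine therapy (RAIT) dose. Implements a
    four-strategy somatic variant filter with a per-variant audit trail,
    the ARCH-PD putative-driver rule engine, maximum-likelihood dN/dS
    selection inference under a 96-class trinucleotide-context neutral
    model, Firth penalized logistic regression with profile-penalized-
    likelihood confidence intervals for sparse CH outcomes, dose-cutoff
    optimization, gene co-occurrence tests, and longitudinal clone-size
    dynamics for paired pre/post-therapy samples. A synthetic-data module
    generates cohorts, truth-labelled variant calls with injected
    artifacts, coding-sequence panels and paired samples so that every
    stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
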