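Package: varprio
Title: Consensus Pathogenicity Classification and Cohort Burden Analysis for APOA5 Coding Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing coding variants in hyperlipidemic acute
    pancreatitis genetics. Implements a SIFT-anchored consensus rule that
    combines six in-silico predictors (SIFT, PolyPhen2-HDIV, LRT,
    MutationTaster, MutationAssessor, CADD) into pathogenic/benign calls,
    an HGVS coding-variant parser and consequence caller, residue-level
    annotation of apoA-V functional domains and amino-acid property
    changes, alignment-column conservation scoring, and case-control
    gene-burden tabulation with group comparisons. A synthetic-cohort
    generator reproduces the carrier structure and clinical moments of a
    two-arm pancreatitis study so the whole pipeline is testable without
    access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
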