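Package: natomics
Title: Multi-Omic Screens for N-Terminal Acetyltransferase Gene Families
Version: 0.1.0
Authors@R: person("Analysis", "Pipelines", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for multi-omic characterisation of the
    N-terminal acetyltransferase (NAT) gene family and similar small gene
    families in cancer cohorts: a rule engine routing protein N-termini to
    NAT complexes and classifying the N-terminal-acetylation consequence of
    missense mutations; mutation and copy-number burden screens with
    ORF-length normalisation and hotspot recurrence detection; a
    tumour-versus-normal differential-expression screen; a DNA-methylation
    versus expression anti-correlation discovery procedure; CRISPR
    gene-effect essentiality, co-dependency and paralog-compensation
    analysis; and an expression-survival association screen (Kaplan-Meier
    median split and univariate Cox regression with Benjamini-Hochberg
    false-discovery control). A synthetic multi-omic cohort generator with
    planted, machine-readable ground-truth signals makes every screen
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
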