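Package: proteoMR
Title: Cis-Mendelian Randomization and Colocalization for Drug-Target
    Discovery from GWAS Summary Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for proteome-wide two-sample Mendelian randomization
    (MR) screens of disease outcomes. Reads, validates and harmonizes
    tabular GWAS and protein quantitative trait locus (pQTL) summary
    statistics; performs fixed-effects inverse-variance-weighted GWAS
    meta-analysis with MAF filtering, lead-variant clumping and novelty
    flagging; selects cis-pQTL instruments per protein-coding gene;
    estimates causal effects by Wald ratio and fixed-effects IVW with
    Cochran's Q and MR-Egger diagnostics and Benjamini-Hochberg FDR
    control; tests for a shared causal variant by approximate-Bayes-factor
    colocalization (posterior probabilities over hypotheses H0-H4); and
    triages candidate genes through a four-step horizontal-pleiotropy
    assessment, risk-factor directionality checks, agonist/inhibitor
    inference and druggability regrouping. A summary-statistics simulator
    with known ground truth under linkage disequilibrium supports
    end-to-end testing without access to restricted cohort data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
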