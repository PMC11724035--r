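Package: cytomr
Title: Cytokine GWAS Meta-Analysis, Fine-Mapping and Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for multi-cohort genome-wide association
    studies of circulating cytokine levels and their downstream causal
    analyses. Implements sample-size-weighted z-score meta-analysis with
    standardized effect reconstruction and Cochran Q heterogeneity, greedy
    LD clumping and independent-locus definition with cis/trans
    classification, cross-assay replication rates, single-causal-variant
    Bayesian fine-mapping with 95% credible sets, LD-score regression for
    SNP-heritability and cross-trait genetic correlation, cis-instrument
    two-sample Mendelian randomization (inverse-variance-weighted, Egger,
    weighted median, Steiger filtering) for cytokine networks and disease
    screens, and enumeration-based Bayesian colocalization. Ships a seeded
    synthetic summary-statistic generator that emulates three proteomics
    cohorts with LD-structured signals so that every estimator can be
    validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
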