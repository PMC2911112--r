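Package: dosage21
Title: Single-Gene Dosage Imbalance Analysis in Mouse ES Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying transcriptional responses to
    single-gene dosage imbalance in mouse embryonic stem cells. Implements
    differential expression with a regularized (Bayesian-style) t-statistic
    and Benjamini-Hochberg FDR control, classification of overexpressed genes
    as transcriptionally effective or silent, prediction of dosage
    sensitivity from basal expression (running-sum gene-set enrichment) and
    intrinsic protein disorder (residue-count threshold classifier),
    sign-concordance of single-gene overexpression signatures with a trisomic
    reference signature via a resampling null and origin-forced regression,
    and two-dimensional gel electrophoresis spot-volume differential
    proteomics with protein-mRNA trend pairing. A synthetic-data generator
    with recorded ground truth emulates the structure of the underlying
    study designs so the full pipeline runs and is tested without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    withr
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
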