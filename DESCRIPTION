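Package: adaptomics
Title: Multi-Omics Analysis of Immediate Drug-Adaptation Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying the immediate molecular
    adaptation of cancer cells to targeted kinase inhibition. Implements
    isobaric-label (TMT 10-plex) proteome quantification by median
    sweeping with picked target/decoy protein FDR, variance-moderated
    protein differential expression with PSM-count-aware empirical-Bayes
    shrinkage, a simplified negative-binomial Wald test for mRNA counts,
    dose-response (4PL) fitting with drug sensitivity scores (DSS) and
    combination-screen synergy scoring (sDSS) with hit calling, consensus
    ChIP-target filtering with candidate-gene derivation, and
    hypergeometric over-representation analysis. A synthetic-data
    generator with planted ground truth makes every stage verifiable
    without access to deposited datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
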