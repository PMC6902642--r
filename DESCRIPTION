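Package: sigmra
Title: Signature-Restricted Master Regulator Analysis of Signalling Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcriptional master regulators of signal-transduction
    pathways from two-condition expression data. Builds a mutual-information
    regulatory network with permutation-based edge significance and data
    processing inequality pruning, derives signed regulons from Spearman
    correlation, scores each regulon by a weighted Kolmogorov-Smirnov gene set
    enrichment statistic against a pathway-restricted Z-normalised differential
    expression signature, and calibrates enrichment scores against a
    label-permutation null model. Also provides principal-curve pathway
    deregulation scores, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, and a synthetic-data generator with planted
    regulatory ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
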