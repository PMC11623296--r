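Package: tdratio
Title: Transcriptomic Distance Ratios Between Tumors and Their Origin and
    Target Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whether primary and metastatic tumor transcriptomes
    are closer to their normal tissue of origin or to their metastatic target
    tissue. Implements sample-level transcriptomic distances on z-scored
    log2 expression (Euclidean, Spearman- and cosine-based), TD ratios and
    their purity-adjusted residuals, organotropism specificity scoring over
    candidate target tissues, pathway-restricted delta ratios and PMT scores
    with random-gene-set empirical p-values and Benjamini-Hochberg FDR,
    geometric-mean fold-change pre-ranked gene-set enrichment with a
    random-set control, a rank-based single-sample activity score, and a
    synthetic cohort generator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    edgeR,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
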