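Package: mrdpanel
Title: Targeted Capture Panel Design for ctDNA Minimal Residual Disease Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs and evaluates targeted-capture sequencing panels for
    tumor-informed circulating tumor DNA (ctDNA) minimal residual disease
    (MRD) assays. Seeds a panel from recurrently mutated exons ranked by a
    per-kilobase-per-sample Recurrence Index, segments exons into compact
    (<= 40 bp) mutation-cluster candidate regions, scores candidates with
    recurrence-improvement features, converts features into informativity
    rates under a Poisson-Binomial model, and screens candidates against a
    regularized multivariate Gaussian fitted to the seed regions using
    squared Mahalanobis distance with a chi-squared acceptance threshold.
    Also provides a binomial cell-free DNA sampling model linking input
    mass and tracked-variant count to the assay limit of detection, panel
    evaluation metrics (variant density, per-patient trackable counts,
    patient coverage), and a seeded synthetic-cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
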