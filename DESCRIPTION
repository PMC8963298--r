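Package: metabscreen
Title: Pre-Analysis Quality Screening for Metabolomics Abundance Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A standardized pre-analysis workflow for curated metabolomics
    abundance matrices. Computes per-sample and per-feature quality
    statistics (missingness, total sum abundance, interquartile-range
    outlier counts, distribution descriptives, Shapiro-Wilk normality),
    selects representative features by Spearman-distance hierarchical
    clustering, detects outlying samples by principal component analysis
    with scree-based component retention (acceleration factor and parallel
    analysis), performs median batch normalization, applies an ordered,
    user-parameterized sample and feature exclusion pipeline with a full
    exclusion log, quantifies batch effects by eta-squared, provides power
    calculations under missing data, and renders a self-contained HTML
    report plus a per-feature plot document. Ships a seeded synthetic data
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
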