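Package: secretopls
Title: Secretome-Based Prediction of Post-Irradiation Survival with
    Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for relating the secreted-protein profile of
    mesenchymal stromal cell (MSC) preparations to the survival of
    irradiated animal cohorts treated with those preparations.  Implements
    a per-timepoint Pearson correlation screen with joint effect-size and
    significance thresholds, a Spearman rank screen of expression against
    culture-substratum stiffness with Bonferroni correction, a
    from-scratch two-component multivariate-response partial least squares
    regression (SIMPLS) with column z-scoring, variance-explained
    accounting, an intercept-augmented coefficient matrix, loading-map and
    loading-proximity biomarker ranking, survival-curve prediction, and
    the downstream validation statistics (Kaplan-Meier curves, median
    survival, Mantel-Cox log-rank test, Mantel-Haenszel hazard ratios,
    one-tailed Welch t tests, family-wise p adjustment).  A seeded
    synthetic-data generator emulates potency-linked secretome and
    survival panels so the whole pipeline is testable without access to
    the original assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
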