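Package: fuzzydx
Title: Data-Driven Mamdani Fuzzy Classifiers for Clinical Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Induces interpretable Mamdani-type fuzzy inference classifiers
    directly from tabular clinical data. Each variable is discretised by Ward
    hierarchical clustering (or k-means) and the per-cluster minima and maxima
    become triangular or trapezoidal membership functions; unique clustered
    training rows become the IF-THEN rule base. A wrapper search sweeps feature
    subsets and cluster counts under random-sampling or k-fold cross-validation
    and scores candidates with accuracy, sensitivity, specificity, F-measure,
    Cohen's kappa and rank-based AUC. Fitted systems round-trip through the
    plain-text 'fis' interchange format, and a seeded generator produces
    classification datasets with known cluster structure for offline testing.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
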