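Package: dsanfis
Title: Interpretable Fuzzy Classification with Dominant-Set Initialized ANFIS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compact, human-readable fuzzy rule-based classifiers for
    binary clinical outcomes from tabular subject-by-attribute data. Subjects
    are connected in a Gaussian-affinity graph; dominant-set clustering via
    replicator dynamics on the simplex, applied with a peeling-off strategy,
    discovers the number of clusters automatically and tolerates unstructured
    clutter. Each cluster becomes a zero-order Takagi-Sugeno-Kang fuzzy rule
    with Gaussian memberships, and the rule base is refined by hybrid ANFIS
    learning (least-squares consequents, gradient-descent premises). Includes
    min-max normalization, mean imputation and correlation screening,
    stratified repeated cross-validation, and synthetic data generators for
    end-to-end testing.
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
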