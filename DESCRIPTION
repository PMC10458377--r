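Package: batterysel
Title: Choosing and Timing Behavioral Test Batteries in Repetitive Mild TBI Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding which combination of behavioral outcome tests,
    and at which week after injury, best discriminates mice with repetitive
    mild traumatic brain injury (rmTBI) from sham controls when data are
    pooled across many small, sparsely overlapping experiments. Provides a
    registry of hierarchically coded behavioral outcomes (category, test,
    parameter family, week), sparse-cohort assembly with availability and
    complete-case profiling, PCA summaries of outcome structure, bootstrapped
    and cross-validated AUC estimation for adjusted logistic classifiers with
    a minimum-sample-size guard, a hierarchical best-model selection cascade
    with missingness-aware maximum-model search, an exhaustive k-means /
    adjusted Rand index combination scan, a study-accumulation analysis of
    heterogeneous experiments scored by standardized RMSE, and a synthetic
    cohort generator that reproduces the design margins such analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
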