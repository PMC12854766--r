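Package: toxhier
Title: Hierarchical Mechanistic Modeling of Toxicity from
    Concentration-Response Screening Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps Hill-parametrized high-throughput-screening
    concentration-response data through a layered assay -> protein ->
    pathway -> toxicity hierarchy. Curves are harmonized on a standard
    logarithmic concentration grid, factorized through masked mapping
    matrices trained by gradient descent, and linked to in vivo endpoints
    by statistical filtering (Pearson and rank tests, Benjamini-Hochberg
    FDR, rank-biserial effect sizes). Includes compound scoring and
    quartile stratification against GHS and NOAEL dose bands,
    Taylor-Butina fingerprint clustering with cluster-level toxicity
    z-scores, comparison of steady-state plasma concentrations against
    modeled EC50 potencies, and a synthetic-study generator with known
    ground truth for end-to-end validation.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
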