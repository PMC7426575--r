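Package: immunocycle
Title: Cancer-Immunity-Cycle Subgrouping of Bulk Tumor Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subgroups bulk tumor expression cohorts by Gaussian-mixture
    clustering over an eight-panel cancer-immune gene registry, labels each
    subgroup with a three-axis immune-escape phenotype (ubiquitination,
    type I interferon production/signaling, antigen presentation), computes
    per-sample signature scores (cytolytic activity, immune/stromal averages,
    tumor mutational burden, arm-level copy-number burden), and classifies
    likely immune-checkpoint-blockade responders with geometric-mean
    tumor-intrinsic (TIC) and immune-response-predictor (IRP) scores.
    Ships a synthetic-cohort generator with planted three-subgroup structure
    so the whole pipeline is testable without external data.
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
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
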