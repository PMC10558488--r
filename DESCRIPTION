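Package: cachexomics
Title: Multi-Omics Integration of Cofactor Stoichiometry and Enzyme Decline in Cancer Cachexia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for integrating tissue metabolome and proteome
    data around cofactor biology. Builds annotation-driven "cofactor objects"
    (NAD, vitamin B6, pantothenate, riboflavin, SAM, ATP, glycine, one-carbon
    units) from a UniProt-style catalog via a small boolean search-formula
    grammar, converts metabolite and protein quantities to a common molar
    scale, and quantifies the near one-to-one metabolite:enzyme stoichiometry
    with log-log regression and gray-zone molar-ratio summaries. Downstream
    statistics cover abundance-dependent enzyme decline (depression slopes,
    high/low by up/down classification with Fisher tests, dummy-variable
    multiple regression with generalized variance-inflation factors),
    compartment-matched proteome resampling with PCA and linear-SVM maximal
    margins, lysine acyl-PTM site competition (shared-site detection,
    protein-adjusted fold changes, many-to-one comparison against
    malonylation), and blood-biomarker trend statistics (permutation
    Jonckheere-Terpstra trend over ordinal severity scores, repeated
    random-forest importance selection, ROC analysis). A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
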