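Package: lipidfun
Title: Functional Lipid Indices from Quantitative Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts a quantitative lipidomics matrix (lipid species in
    LIPID MAPS shorthand by samples) into a curated panel of 42
    biochemically defined functional indices covering membrane structure,
    lipid signaling and energy metabolism. Provides a rule-based shorthand
    parser, per-sample index computation with explicit missing-value
    semantics, Welch-based group comparison with delta-method standard
    errors on the log2 fold change, functional dominance summaries,
    biomarker ranking (ROC AUC, Cohen's d, post-hoc power), PCA and PLS-DA
    with VIP scores, clustered heatmaps over seven distance measures,
    reaction-balance enzyme direction calls, offline STRING network request
    construction, and a synthetic-study generator with planted index-level
    effects.
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
    mixOmics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
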